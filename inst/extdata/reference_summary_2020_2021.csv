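country,average,sd,minimum,maximum,range,dw1,dw2,dw3
Australia,-9.5,3.0,-15.7,-2.6,13.1,-7.6,-8.9,-4.8
Austria,2.8,3.0,-3.7,8.8,12.5,4.7,3.4,7.1
Belgium,0.9,3.0,-5.5,8.3,13.8,2.8,1.5,5.4
Canada,0.1,2.0,-6.9,4.8,11.8,1.3,0.5,2.8
Switzerland,-1.5,3.0,-8.3,5.5,13.8,0.4,-0.9,3.4
Chile,6.4,3.9,-1.7,15.0,16.8,8.8,7.2,12.8
Czechia,10.2,3.9,1.0,18.0,16.9,12.6,11.0,15.5
Germany,1.1,1.9,-4.3,4.6,8.9,2.2,1.5,3.1
Denmark,-7.6,4.0,-18.6,-0.2,18.3,-5.1,-6.8,-2.9
Spain,3.6,2.2,-2.6,10.9,13.5,4.9,4.0,7.1
Estonia,0.8,4.8,-11.6,10.1,21.7,3.8,1.8,7.1
Europe,2.5,2.2,-3.5,7.8,11.3,3.8,2.9,5.6
Finland,-5.3,3.1,-11.8,1.6,13.4,-3.3,-4.6,-0.9
France,2.6,2.0,-3.6,6.4,10.0,3.8,3.0,5.0
United Kingdom,4.2,1.9,-1.2,10.1,11.3,5.3,4.5,7.1
Greece,5.6,2.8,-1.3,10.7,12.0,7.2,6.2,8.4
Croatia,7.0,3.1,-1.2,14.9,16.1,8.9,7.7,11.5
Hungary,6.8,2.7,0.5,13.1,12.6,8.5,7.4,10.5
Iceland,-7.3,2.1,-12.2,-2.1,10.1,-6.4,-7.0,-4.4
Israel,-1.5,2.9,-7.0,4.6,11.6,0.3,-0.9,2.7
Italy,5.5,2.4,-0.4,10.8,11.2,6.9,5.9,8.9
South Korea,-13.8,5.3,-24.7,-1.2,23.5,-10.4,-12.7,-5.8
Lithuania,8.6,3.3,2.1,18.8,16.8,10.6,9.3,14.4
Luxembourg,-2.8,3.9,-10.7,3.8,14.5,-0.5,-2.0,1.4
Latvia,7.1,3.2,-1.0,14.0,15.0,9.0,7.7,11.1
Netherlands,2.5,2.0,-2.5,7.8,10.4,3.7,2.9,5.4
Norway,-9.4,3.6,-16.0,-1.4,14.7,-7.1,-8.6,-3.9
New Zealand,-9.1,2.5,-15.5,-4.2,11.3,-7.6,-8.6,-6.1
Poland,14.3,3.5,4.0,19.9,15.9,16.4,15.0,17.9
Portugal,2.8,2.7,-4.4,8.1,12.5,4.5,3.4,6.2
Slovakia,9.9,4.4,0.3,20.3,20.0,12.7,10.8,16.4
Slovenia,4.7,3.4,-4.0,11.8,15.7,6.8,5.4,9.4
Sweden,-6.7,3.4,-12.4,4.2,16.7,-4.5,-6.0,-0.7
United States,16.7,0.8,14.4,18.7,4.3,17.1,16.8,17.7
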