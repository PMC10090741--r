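country,p2020,p2021,p_2yr,p_3yr,p_4yr,drop_2,drop_3,drop_4
Australia,-10.6,-8.4,-9.5,-8.5,-8.2,1.1,0.2,-0.2
Austria,3.2,2.4,2.8,0.1,-0.9,0.4,3.2,4.1
Belgium,7.5,-5.5,0.9,-1.6,-2.1,6.5,9.1,9.6
Canada,0.5,-0.3,0.1,-1.4,-1.5,0.4,1.9,2.1
Chile,3.1,9.7,6.4,1.9,-0.2,3.2,7.7,9.9
Croatia,2.0,12.0,7.0,2.4,0.9,5.0,9.6,11.2
Czechia,6.4,14.0,10.2,4.7,2.5,3.8,9.3,11.5
Denmark,-8.6,-6.5,-7.6,-7.5,-6.4,1.0,0.9,-0.2
Estonia,-6.5,8.0,0.8,-2.3,-3.0,7.2,10.3,11.0
Finland,-6.1,-4.5,-5.3,-5.8,-5.3,0.8,1.2,0.8
France,3.9,1.3,2.6,0.6,-0.1,1.3,3.3,4.0
Germany,-0.1,2.4,1.1,-0.3,-0.4,1.2,2.7,2.7
Greece,1.1,10.1,5.6,3.1,1.2,4.4,7.0,8.9
Hungary,1.7,11.9,6.8,2.7,1.4,5.1,9.2,10.6
Iceland,-7.0,-7.6,-7.3,-6.6,-6.1,0.3,-0.4,-1.0
Israel,-2.1,-0.9,-1.5,-2.6,-3.3,0.6,1.6,2.4
Italy,8.9,2.1,5.5,2.1,0.5,3.4,6.8,8.3
Latvia,-2.5,16.6,7.1,2.7,1.4,9.5,13.9,15.2
Lithuania,3.9,13.4,8.6,2.9,0.9,4.7,10.5,12.5
Luxembourg,-0.5,-5.0,-2.8,-3.9,-3.7,2.3,3.4,3.2
Netherlands,3.3,1.8,2.5,0.1,-0.4,0.7,3.2,3.7
New Zealand,-10.7,-7.5,-9.1,-7.4,-6.7,1.6,-0.1,-0.8
Norway,-10.1,-8.6,-9.4,-8.9,-8.2,0.7,0.3,-0.5
Poland,10.4,18.1,14.3,8.2,5.7,3.8,9.9,12.4
Portugal,3.6,2.0,2.8,0.3,-0.3,0.8,3.3,3.9
Slovakia,-0.4,19.9,9.9,3.8,1.7,10.0,16.1,18.3
Slovenia,7.5,1.9,4.7,1.0,-0.3,2.9,6.5,7.9
South Korea,-13.8,-13.7,-13.8,-13.4,-12.1,0.1,-0.3,-1.6
Spain,8.7,-1.5,3.6,0.2,-0.4,5.1,8.5,9.1
Sweden,-2.4,-10.8,-6.7,-7.9,-7.2,4.2,5.4,4.7
Switzerland,2.9,-5.8,-1.5,-3.2,-3.7,4.4,6.1,6.6
United Kingdom,6.1,2.3,4.2,1.0,0.3,1.9,5.0,5.8
United States,15.7,17.6,16.7,10.6,7.8,1.0,7.0,9.9
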