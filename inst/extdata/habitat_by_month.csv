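habitat,Jan,Feb,Mar,Apr,May,Jun,Jul,Aug,Sep,Oct,Nov,Dec
Low shrubland,2351,1999,2312,2241,2900,3019,3156,2963,2672,2634,2187,2659
Non-vegetated,158,140,86,8,34,18,15,50,80,42,25,129
Dense bush,203,340,453,137,195,7,14,194,264,321,788,144
Open bush,120,4,102,191,67,41,20,19,115,174,121,31
Grassland,2,1,36,1,25,0,0,0,64,55,41,163
Wetlands,3,6,5,0,0,0,0,0,0,2,1,0
Cultivated commercial fields,0,31,127,3,0,0,0,0,0,40,0,0
Water permanent,0,0,6,0,0,0,0,0,0,0,0,0
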