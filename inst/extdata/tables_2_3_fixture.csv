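group,current_descriptions,authors_per_year,public_interest,body_size,soil_endo,aquatic,region_fraction,future_ratio,initial_time,residual_ss
Tracheophyta,354344,285.3,341495,2,1,1,0.37,1.00,64,0.00039
Marchantiophyta,7208,5.6,32,0,1,1,0.33,1.29,109,0.00095
Bryophyta,11049,11.6,4507,1,1,1,0.40,1.00,84,0.00210
Chlorophyta,5512,7.6,92,-1,1,5,0.83,1.07,117,0.00014
Rhodophyta,7197,8.3,122,2,1,5,0.71,1.36,98,0.00059
Ochrophyta,31162,24.5,25,-2,1,5,0.70,1.01,96,0.00097
Oomycota,1670,3.1,0,0,3,2,0.78,1.01,139,0.00086
Foraminifera,30026,15.5,0,-1,3,5,0.69,1.09,113,0.00136
Ciliophora,8582,7.8,4,-1,3,3,0.75,1.00,113,0.00067
Myzozoa,9014,15.1,1,-2,4,2,0.81,1.08,151,0.00022
Haptophyta,432,0.8,2,-3,1,5,0.85,1.01,183,0.00043
Euglenozoa,2521,3.9,0,-2,1,5,0.77,1.00,143,0.00010
Amoebozoa,2936,5.1,0,-1,3,3,0.89,1.50,122,0.00052
Chordata,74981,84.3,434058,2,1,2,0.39,1.01,60,0.00102
Platyhelminthes,20258,22.8,639,0,4,2,0.50,1.23,142,0.00015
Gastrotricha,831,0.9,0,0,1,5,0.76,2.24,161,0.00024
Ectoprocta,5870,3.2,1,-1,1,5,0.61,1.07,100,0.00085
Mollusca,98947,64.4,8855,1,1,4,0.53,1.00,70,0.00127
Nemertea,1349,1.3,0,1,4,5,0.58,1.01,98,0.00126
Annelida,22326,21.1,1597,1,2,4,0.48,1.19,114,0.00054
Lepidoptera,148522,90.3,28026,1,1,1,0.30,1.02,87,0.00221
Trichoptera,16976,7.7,0,1,1,1,0.42,5.86,150,0.00016
Diptera,219245,81.2,7816,0,1,1,0.46,1.05,109,0.00027
Siphonaptera,2621,3.2,1473,0,1,1,0.46,1.05,138,0.00083
Coleoptera,421378,135.6,3121,0,1,1,0.42,1.00,81,0.00056
Neuroptera,6847,4.2,1,1,1,1,0.31,1.05,114,0.00107
Hymenoptera,172007,64.1,11181,0,1,1,0.48,1.03,101,0.00050
Hemiptera,116521,57.1,432,1,1,1,0.40,1.12,115,0.00011
Psocodea,11612,5.8,201,0,1,1,0.40,2.02,141,0.00023
Thysanoptera,6826,4.2,15,-1,1,1,0.42,1.00,144,0.00155
Plecoptera,4140,3.9,1,1,1,5,0.48,1.63,153,0.00013
Dermaptera,2226,1.4,163,1,1,1,0.25,1.06,117,0.00109
Dictyoptera,11168,7.0,504,1,1,1,0.50,1.00,108,0.00065
Orthoptera,32041,16.4,14742,1,1,1,0.26,1.01,110,0.00071
Ephemeroptera,5056,5.1,37,1,1,5,0.43,1.36,138,0.00039
Odonata,6869,5.8,1302,1,1,1,0.26,1.00,92,0.00054
Crustacea,72451,60.3,3261,1,1,5,0.44,1.64,121,0.00026
Myriapoda,18678,7.4,433,1,1,1,0.49,1.00,121,0.00051
Arachnida,138514,82.3,7328,1,1,1,0.39,1.43,130,0.00023
Tardigrada,1215,1.9,5,-1,2,3,0.55,3.37,173,0.00023
Nematoda,29527,32.1,28,0,4,3,0.55,1.07,161,0.00029
Cnidaria,12785,12.0,620,1,1,5,0.51,1.01,91,0.00114
Porifera,8724,5.0,2487,1,1,5,0.44,1.00,98,0.00284
Basidiomycota,48428,41.3,2203,1,5,1,0.62,1.29,145,0.00021
Ascomycota,87760,76.2,325,1,5,1,0.63,1.26,141,0.00045
Chytridiomycota,977,1.5,0,-2,4,3,0.78,1.00,143,0.00052
Microsporidia,1155,2.3,0,-3,5,3,0.77,1.27,181,0.00102
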