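group,site_id,treatment,seed_yield,protein,oil,rau_r6
high,Devils Lake,control,3349,40.2,17.3,93
high,Devils Lake,N_sowing,3445,41.6,16.7,84
high,Devils Lake,N_V4,3482,40.0,17.7,85
high,Devils Lake,N_R2,3296,40.8,17.6,73
high,Vincent,control,5717,36.3,20.9,91
high,Vincent,N_sowing,5997,36.2,20.7,87
high,Vincent,N_V4,6044,34.7,20.7,86
high,Vincent,N_R2,6137,35.7,20.6,89
high,Pocahontas,control,5023,37.1,21.1,90
high,Pocahontas,N_sowing,5117,36.9,21.3,88
high,Pocahontas,N_V4,4964,35.6,20.8,88
high,Pocahontas,N_R2,5155,36.9,20.3,89
high,Britt,control,5348,36.8,20.9,89
high,Britt,N_sowing,5211,35.7,21.3,84
high,Britt,N_V4,5118,37.1,21.0,83
high,Britt,N_R2,5234,36.5,20.9,87
high,Thayer,control,5069,36.2,21.8,88
high,Thayer,N_sowing,4855,37.7,21.3,74
high,Thayer,N_V4,4978,36.8,20.7,68
high,Thayer,N_R2,4773,38.7,21.3,42
high,Tipton,control,4614,40.4,20.6,88
high,Tipton,N_sowing,4529,39.8,21.1,86
high,Tipton,N_V4,4247,40.9,20.8,80
high,Tipton,N_R2,4466,40.6,20.7,66
medium,Fargo,control,3344,38.7,20.7,87
medium,Fargo,N_sowing,3451,39.2,20.2,76
medium,Fargo,N_V4,3634,38.1,20.8,68
medium,Fargo,N_R2,3459,38.6,20.2,83
medium,Effingham,control,4405,40.5,22.0,85
medium,Effingham,N_sowing,4435,39.9,21.7,86
medium,Effingham,N_V4,4445,40.2,21.6,84
medium,Effingham,N_R2,4478,38.6,22.0,79
medium,Attica,control,4902,38.3,21.2,84
medium,Attica,N_sowing,4902,38.1,21.1,83
medium,Attica,N_V4,5268,40.4,20.7,77
medium,Attica,N_R2,5206,38.7,21.5,80
medium,Owensboro,control,4731,38.6,21.2,81
medium,Owensboro,N_sowing,4618,36.5,21.1,86
medium,Owensboro,N_V4,4698,39.4,20.4,75
medium,Owensboro,N_R2,4471,39.5,21.4,76
medium,Portland,control,4803,36.8,22.4,81
medium,Portland,N_sowing,4921,37.1,21.7,78
medium,Portland,N_V4,5116,40.5,21.3,74
medium,Portland,N_R2,4856,38.9,22.3,56
medium,Mayville,control,4260,35.1,19.9,80
medium,Mayville,N_sowing,4314,36.7,20.1,72
medium,Mayville,N_V4,4263,36.8,19.7,64
medium,Mayville,N_R2,4569,35.1,20.5,67
medium,Clarksdale,control,5431,38.7,22.1,79
medium,Clarksdale,N_sowing,4965,37.4,21.9,82
medium,Clarksdale,N_V4,5229,37.9,21.6,73
medium,Clarksdale,N_R2,5229,37.6,21.9,71
medium,Wamego,control,5448,37.2,20.2,79
medium,Wamego,N_sowing,4529,35.9,20.8,49
medium,Wamego,N_V4,5298,37.3,20.3,70
medium,Wamego,N_R2,5233,36.9,20.5,59
medium,Blencoe,control,5466,35.6,21.2,77
medium,Blencoe,N_sowing,5304,34.2,21.8,72
medium,Blencoe,N_V4,5513,35.2,21.4,75
medium,Blencoe,N_R2,5383,34.4,21.8,77
medium,Le Sueur,control,4524,36.1,21.4,77
medium,Le Sueur,N_sowing,5042,34.5,22.4,77
medium,Le Sueur,N_V4,4625,31.9,23.0,68
medium,Le Sueur,N_R2,4996,36.2,21.6,70
medium,West Salem,control,5826,37.4,23.0,73
medium,West Salem,N_sowing,5634,40.1,21.3,66
medium,West Salem,N_V4,5667,39.6,22.2,51
medium,West Salem,N_R2,5729,39.9,21.9,60
medium,Holloway,control,5166,35.2,21.7,72
medium,Holloway,N_sowing,6150,35.7,21.7,65
medium,Holloway,N_V4,6060,39.2,19.9,60
medium,Holloway,N_R2,6204,36.9,21.2,57
low,Beaver Dam,control,5132,NA,NA,72
low,Beaver Dam,N_sowing,5304,NA,NA,62
low,Beaver Dam,N_V4,5094,NA,NA,55
low,Beaver Dam,N_R2,5307,NA,NA,72
low,Springfield,control,4911,38.4,20.2,69
low,Springfield,N_sowing,4602,37.7,22.3,63
low,Springfield,N_V4,4784,36.5,22.4,56
low,Springfield,N_R2,4730,36.7,22.5,59
low,Ithaca,control,4128,36.9,21.3,60
low,Ithaca,N_sowing,3976,36.0,20.7,68
low,Ithaca,N_V4,3934,36.0,21.2,73
low,Ithaca,N_R2,4566,35.5,20.4,60
low,Pierre,control,6201,33.1,23.9,57
low,Pierre,N_sowing,6232,33.8,23.0,46
low,Pierre,N_V4,6248,36.1,22.4,63
low,Pierre,N_R2,6326,34.5,23.3,56
low,Van Wert,control,4979,40.1,20.6,48
low,Van Wert,N_sowing,4913,40.4,20.8,57
low,Van Wert,N_V4,5282,41.0,20.6,54
low,Van Wert,N_R2,5204,41.8,20.2,53
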