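arm,category,median,min,max
EUS-BD,hospital_other_cost,3018.78,1036.13,9107.64
EUS-BD,primary_bd_cost,1029.15,1029.15,1313.97
EUS-BD,reintervention_cost,174.21,0,1649.80
EUS-BD,total_bd_cost,1203.36,1029.15,2963.76
EUS-BD,total_cost,4175.53,2065.28,10343.67
PTBD,hospital_other_cost,3612.65,1154.37,13092.19
PTBD,primary_bd_cost,1177.21,763.44,1876.01
PTBD,reintervention_cost,340.62,0,1792.59
PTBD,total_bd_cost,1517.83,1177.21,2969.79
PTBD,total_cost,5391.87,2505.12,14269.40
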