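patient_id,motor_adm,cognitive_adm,motor_dis,cognitive_dis,anchor
SYN00001,33,18,47,24,0
SYN00002,56,14,58,25,1
SYN00003,76,18,91,24,0
SYN00004,60,19,73,21,1
SYN00005,39,18,63,22,1
SYN00006,32,33,67,35,1
SYN00007,43,16,70,16,1
SYN00008,49,17,77,18,1
SYN00009,60,21,86,22,1
SYN00010,33,16,53,20,1
SYN00011,18,8,27,13,1
SYN00012,39,35,80,35,0
SYN00013,59,23,61,25,0
SYN00014,75,18,91,28,1
SYN00015,63,22,66,23,1
SYN00016,52,23,91,32,1
SYN00017,71,16,69,18,0
SYN00018,58,23,76,33,1
SYN00019,56,26,91,35,1
SYN00020,18,19,40,19,1
SYN00021,20,27,44,32,1
SYN00022,27,5,13,10,0
SYN00023,40,18,55,32,1
SYN00024,13,7,33,9,1
SYN00025,54,16,91,17,0
SYN00026,38,15,78,13,1
SYN00027,13,23,13,34,1
SYN00028,24,13,60,19,1
SYN00029,48,10,61,13,0
SYN00030,76,21,90,28,1
SYN00031,46,35,68,35,1
SYN00032,90,21,85,23,1
SYN00033,36,21,56,26,1
SYN00034,43,24,68,25,0
SYN00035,39,33,91,35,1
SYN00036,33,35,50,35,1
SYN00037,32,14,18,17,1
SYN00038,21,24,43,32,1
SYN00039,16,11,16,12,0
SYN00040,13,12,32,12,1
SYN00041,19,16,25,18,1
SYN00042,34,21,56,21,1
SYN00043,66,22,91,35,1
SYN00044,46,16,69,21,1
SYN00045,67,32,75,35,1
SYN00046,32,6,51,16,1
SYN00047,83,23,91,25,0
SYN00048,13,18,20,26,1
SYN00049,27,26,66,32,1
SYN00050,13,15,32,16,0
SYN00051,34,5,43,6,0
SYN00052,21,35,39,35,1
SYN00053,39,16,51,33,0
SYN00054,46,17,48,24,0
SYN00055,13,27,22,30,0
SYN00056,58,21,70,21,1
SYN00057,57,25,61,35,0
SYN00058,71,24,80,35,1
SYN00059,44,13,76,14,1
SYN00060,13,32,22,30,1
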