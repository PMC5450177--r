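record,k,h_R,h_L,clinical
E0111,0.71,0.97,0.95,myocardial_ischemia
E0112,0.79,0.89,0.87,myocardial_ischemia
E0113,0.69,0.91,0.93,myocardial_ischemia
E0114,0.63,0.93,0.92,myocardial_ischemia
E0115,0.96,0.99,0.91,myocardial_ischemia
E0116,0.71,0.88,0.92,myocardial_ischemia
E0117,0.73,0.89,0.88,myocardial_ischemia
E0118,0.71,0.91,0.87,myocardial_ischemia
E0112,0.69,0.91,0.93,myocardial_ischemia
E0113,0.63,0.93,0.92,myocardial_ischemia
E0114,0.66,0.89,0.91,myocardial_ischemia
E0115,0.71,0.88,0.92,myocardial_ischemia
E0116,0.70,0.86,0.88,myocardial_ischemia
E0117,0.79,0.87,0.87,myocardial_ischemia
E0118,0.63,0.91,0.93,myocardial_ischemia
Chf01,1.79,0.81,0.83,heart_failure
Chf02,1.62,0.79,0.81,heart_failure
Chf03,1.16,0.91,0.97,heart_failure
Chf04,1.70,0.86,0.88,heart_failure
Chf05,1.69,0.79,0.86,heart_failure
Chf06,1.79,0.87,0.83,heart_failure
Chf07,1.62,0.79,0.81,heart_failure
Chf08,1.66,0.81,0.77,heart_failure
Chf09,1.10,0.92,0.98,heart_failure
Chf10,1.69,0.99,0.86,heart_failure
Chf11,1.79,0.89,0.83,heart_failure
Chf12,1.62,0.89,0.81,heart_failure
Chf13,1.65,0.81,0.77,heart_failure
Chf14,1.71,0.82,0.88,heart_failure
Chf15,1.68,0.79,0.86,heart_failure
Person_01/rec_1,1.01,0.98,0.99,normal
Person_01/rec_1,1.02,1.04,1.01,normal
Person_01/rec_1,0.99,1.02,0.97,normal
Person_01/rec_1,1.01,0.97,0.99,normal
Person_01/rec_1,1.05,0.99,1.02,normal
Person_01/rec_1,1.01,0.98,0.99,normal
Person_01/rec_1,1.04,0.98,0.99,normal
Person_01/rec_1,1.02,1.01,1.01,normal
Person_01/rec_1,0.99,1.02,0.97,normal
Person_01/rec_1,1.01,0.97,0.99,normal
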