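"RMA","CPE","LEN","WID","THI","EPA","SHA","BUL","ESC","LIP","HCO","PTY","PWI","PTH","NNU","NOR","group"
"1",0,34.39,26.3,,91.74,"1","3","0","0","0","2",20.53,4.35,"2","5","1"
"1",0,21.07,22.05,6.16,87.51,"1","1","0","0","0",,10.61,8.16,"1",,"1"
"1",0,16.29,22.96,11.47,77.09,"1","2","0",,"0","2",14.95,4.84,"2","4","1"
"1",,27.17,26.6,7.67,86.35,"3","5","0","0","0","3",23.16,4.33,"3","1","1"
"3",65.69,22.15,17.67,4.17,84.81,"5","3","0","1","0","2",12.41,2.42,,,"1"
"3",0,37.35,28.59,9.16,76.91,"1","3","0","0","0","2",14.28,4.07,"2","5","1"
"1",0,19.8,25.97,10.38,75.51,"5","3","0","0","0","1",20.78,4.4,"1","1","1"
"1",0,31.09,23.43,5.7,80.63,"5","3","0","0","0","1",21.01,8.64,"4","2","1"
"1",0,24.34,29.11,8.03,82.08,"1","3","0","0","0","2",18.81,10.42,"3","1","2"
"1",0,51.94,44.03,9.68,87.38,"4","2",,"0","0","2",17.53,4.89,"5","4","2"
"4",,,35.77,9.59,94.89,"5","4","0","0","0","2",26.64,6.06,"2","4","2"
"1",0,27.63,44.5,8.56,76.14,"3","2","0","0","0","3",21.1,2.56,"3","1","2"
"1",0,30.62,19.29,9.39,77.74,"2","4","0","0","0","2",,4.67,,"4","2"
"3",1.07,25.52,28.03,9.92,71.01,"1","3","0","0","0","3",9.27,4.33,"4",,"2"
"1",0,,38.71,8.57,69.75,"4","4","0","0","0","2",15.66,4.51,"3","5","2"
"2",0,36.09,38.27,6.83,98.74,"5","5","0","0","0","2",,7.32,,"1","2"
"1",0,29.22,41.39,7.15,83.63,,"2","0","0","0","3",12.81,4.55,"4","4","2"
"1",,38.92,28.39,11.08,92.11,"5","3","0","1","0","5",13.95,9.57,"3","1","2"
"5",0,20.82,46.37,10.51,,"3",,,"1","0","2",10.97,,,"4","2"
"3",0,25.66,32.2,8.24,88.22,"4","3","0","0","0","2",12.56,4.36,"4",,"2"
"1",67.54,31.36,32.37,5.9,91.12,"4","5","0","0","0","2",12.36,8.04,"3","2","2"
"1",0,37.33,25.72,6.37,93.77,"5","3","0","0","0","2",13.86,3.43,"3","1","2"
"1",11.6,35.2,32.9,9.23,90.89,,"5","0","0","0","2",19.17,4.47,"3","1","2"
"1",0,36.84,31.33,8.13,80.08,"3","3","0","0","0","4",,5.57,"5","1","2"
"1",0,45.6,34.86,9.41,,"5","3","0",,,"2",18.44,4.94,"4","4","2"
"1",17.13,27.94,30.14,7.87,95.43,"5",,"0","0","0","2",11.92,4.11,"4","4","3"
"1",0,44.89,,7.57,,"1","2",,"0","0","1",15.7,3.03,"3","5","3"
"1",61.12,75.47,57.6,10.48,83.56,,"4","0","0","0","2",17.91,5.08,"6","2","3"
"1",16.3,24.89,29.04,,,"5",,"0","0","0","2",24.18,3.19,"3","4","3"
"1",,45.43,22.93,9.12,98.67,"4","2","0","0","0","1",22.4,9.11,"2","5","3"
"3",0,31.61,19.69,5.99,74.01,"2",,"0","0","0","2",15.76,5.38,,"4","3"
,0,36.35,64.71,,,"4","4","0","0","0","2",16.25,14.86,,"1","4"
"2",0,61.28,59.29,5.71,76.62,"4","2","0","0","0","2",,3.15,"4","5","4"
"1",52.81,38.78,33.85,10.16,80.93,"1","4","1",,"0","2",19.15,7.79,"5","1","4"
"1",0,45.65,47.7,6.07,,"2","3","0",,"0","2",23.05,5.73,,"1","4"
"1",36.56,38.38,27.55,19.75,87.34,"2","3","0",,"0","2",26.94,,"5","2","4"
"1",0,41.6,35.88,11.59,86.9,"2","5",,"0","1","2",,6.89,"3","1","4"
"1",0,23.09,27.38,6.28,85.09,"1","4",,"0","0","2",7.02,,"3","4","4"
,0,,16.95,11.6,93.34,"1","3","0",,,"2",7.34,4.89,"4","2","4"
"1",17.48,65.16,63.26,18.02,86.69,"1","4","0",,"0","3",,5.49,"4","4","4"
"3",21.05,55.07,63.9,16.28,76.86,"1","4","0","0","0","2",25.82,12.56,"3","5","4"
"1",0,46.25,61.62,,71.47,"2","3","0","0",,"2",14.23,,"7","5","4"
"2",0,55.23,57.76,27.45,70.97,"1","4","0","0",,"2",41.28,6.36,,"1","4"
"1",0,31.79,38.64,7.26,83.47,"5","3","0","0","0","6",10.98,5.44,"2","4","4"
"1",0,61.36,49.53,9.96,91.91,"4","5","0","0","0","6",15.34,3.69,"3","2","4"
"1",67.63,37.01,25.69,8.38,80.24,"2","4","0",,"0","2",,,"2","1","4"
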