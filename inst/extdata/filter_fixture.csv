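subject_id,sex,age,weight,height,insulin,glucose,a1c,hdl,tg,medications,yearly_exam_count
P01,F,30,60,1.60,6.2,99,5.6,50,149,,1
P02,F,35,100,2.00,7.1,90,5.2,60,100,,1
P03,M,40,70,1.75,5.9,100,5.3,45,110,,1
P04,M,45,72,1.80,8.0,95,5.7,48,120,,1
P05,F,50,55,1.55,5.5,90,5.4,58,150,,1
P06,F,28,58,1.62,6.8,88,5.2,49.9,120,,1
P07,M,33,75,1.82,7.4,92,5.5,40,140,,1
P08,M,38,68,1.78,6.0,89,5.1,52,95,antihypertensive,1
P09,F,42,52,1.68,5.2,87,5.0,63,85,,1
P10,F,55,61,1.65,6.5,91,5.3,55,99,,2
P11,F,44,57,1.65,5.8,85,5.1,65,80,,1
P12,M,25,80,1.90,6.9,85,5.0,55,90,,2
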