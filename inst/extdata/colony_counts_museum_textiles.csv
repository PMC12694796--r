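sample_id,arm,test,ncc_or_mark,dilution_factor,volume_plated_ml
1,untreated,t1,12,50,1
1,treated,t1,3,50,1
1,untreated,t2,uncountable,50,1
1,treated,t2,below_detection,50,1
2,untreated,t1,below_detection,50,1
2,treated,t1,2,50,1
2,untreated,t2,9,50,1
2,treated,t2,3,50,1
3,untreated,t1,below_detection,50,1
3,treated,t1,2,50,1
3,untreated,t2,27,50,1
3,treated,t2,2,50,1
4,untreated,t1,4,50,1
4,treated,t1,below_detection,50,1
4,untreated,t2,uncountable,50,1
4,treated,t2,below_detection,50,1
5,untreated,t1,5,50,1
5,treated,t1,3,50,1
5,untreated,t2,107,50,1
5,treated,t2,2,50,1
6,untreated,t1,below_detection,50,1
6,treated,t1,4,50,1
6,untreated,t2,below_detection,50,1
6,treated,t2,2,50,1
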