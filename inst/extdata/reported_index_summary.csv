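model,index,statistic,value
KNN,precision,MIN,0.5000
KNN,precision,AVG,0.6506
KNN,precision,STD,0.1490
KNN,precision,MAX,0.8571
SVM,precision,MIN,0.8571
SVM,precision,AVG,0.8857
SVM,precision,STD,0.0639
SVM,precision,MAX,1.0000
SCUCC,precision,MIN,0.7000
SCUCC,precision,AVG,0.9067
SCUCC,precision,STD,0.1362
SCUCC,precision,MAX,1.0000
CLCBR,precision,MIN,0.6000
CLCBR,precision,AVG,0.7633
CLCBR,precision,STD,0.1529
CLCBR,precision,MAX,1.0000
ETCBR,precision,MIN,0.7500
ETCBR,precision,AVG,0.8917
ETCBR,precision,STD,0.1087
ETCBR,precision,MAX,1.0000
LWCBR,precision,MIN,0.3333
LWCBR,precision,AVG,0.6578
LWCBR,precision,STD,0.1985
LWCBR,precision,MAX,0.8000
RWCBR,precision,MIN,0.7778
RWCBR,precision,AVG,0.9111
RWCBR,precision,STD,0.1217
RWCBR,precision,MAX,1.0000
KNN,recall,MIN,0.7143
KNN,recall,AVG,0.8285
KNN,recall,STD,0.0639
KNN,recall,MAX,0.8571
SVM,recall,MIN,0.8571
SVM,recall,AVG,0.8857
SVM,recall,STD,0.0639
SVM,recall,MAX,1.0000
SCUCC,recall,MIN,0.2857
SCUCC,recall,AVG,0.6857
SCUCC,recall,STD,0.2748
SCUCC,recall,MAX,1.0000
CLCBR,recall,MIN,0.5714
CLCBR,recall,AVG,0.7714
CLCBR,recall,STD,0.1917
CLCBR,recall,MAX,1.0000
ETCBR,recall,MIN,0.7143
ETCBR,recall,AVG,0.8571
ETCBR,recall,STD,0.1429
ETCBR,recall,MAX,1.0000
LWCBR,recall,MIN,0.2857
LWCBR,recall,AVG,0.7428
LWCBR,recall,STD,0.3097
LWCBR,recall,MAX,1.0000
RWCBR,recall,MIN,0.7143
RWCBR,recall,AVG,0.9143
RWCBR,recall,STD,0.1278
RWCBR,recall,MAX,1.0000
KNN,f1,MIN,0.5882
KNN,f1,AVG,0.7236
KNN,f1,STD,0.1067
KNN,f1,MAX,0.8571
SVM,f1,MIN,0.8571
SVM,f1,AVG,0.8857
SVM,f1,STD,0.0639
SVM,f1,MAX,1.0000
SCUCC,f1,MIN,0.4444
SCUCC,f1,AVG,0.7375
SCUCC,f1,STD,0.1795
SCUCC,f1,MAX,0.9231
CLCBR,f1,MIN,0.6154
CLCBR,f1,AVG,0.7576
CLCBR,f1,STD,0.1514
CLCBR,f1,MAX,1.0000
ETCBR,f1,MIN,0.7692
ETCBR,f1,AVG,0.8672
ETCBR,f1,STD,0.0965
ETCBR,f1,MAX,1.0000
LWCBR,f1,MIN,0.3077
LWCBR,f1,AVG,0.6861
LWCBR,f1,STD,0.2320
LWCBR,f1,MAX,0.8750
RWCBR,f1,MIN,0.8333
RWCBR,f1,AVG,0.9013
RWCBR,f1,STD,0.0637
RWCBR,f1,MAX,1.0000
KNN,g,MIN,0.5976
KNN,g,AVG,0.7221
KNN,g,STD,0.1088
KNN,g,MAX,0.8571
SVM,g,MIN,0.8571
SVM,g,AVG,0.8857
SVM,g,STD,0.0639
SVM,g,MAX,1.0000
SCUCC,g,MIN,0.5345
SCUCC,g,AVG,0.7649
SCUCC,g,STD,0.1451
SCUCC,g,MAX,0.9258
CLCBR,g,MIN,0.6171
CLCBR,g,AVG,0.7624
CLCBR,g,STD,0.1488
CLCBR,g,MAX,1.0000
ETCBR,g,MIN,0.7715
ETCBR,g,AVG,0.8708
ETCBR,g,STD,0.0951
ETCBR,g,MAX,1.0000
LWCBR,g,MIN,0.3086
LWCBR,g,AVG,0.6931
LWCBR,g,STD,0.2345
LWCBR,g,MAX,0.8819
RWCBR,g,MIN,0.8452
RWCBR,g,AVG,0.9070
RWCBR,g,STD,0.0593
RWCBR,g,MAX,1.0000
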