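channel	ID1	ID2	ID8
1:Del:C:0	0.00052	0.00052	0.0005094
1:Del:C:1	0.00052	0.00052	0.0005094
1:Del:C:2	0.00052	0.00052	0.0005094
1:Del:C:3	0.00052	0.00052	0.0005094
1:Del:C:4	0.00052	0.00052	0.0005094
1:Del:C:5	0.00052	0.0525221	0.0005094
1:Del:T:0	0.00052	0.00052	0.0005094
1:Del:T:1	0.00052	0.00052	0.0005094
1:Del:T:2	0.00052	0.00052	0.0005094
1:Del:T:3	0.00052	0.0733229	0.0005094
1:Del:T:4	0.00052	0.2085283	0.0005094
1:Del:T:5	0.00052	0.6245467	0.0005094
1:Ins:C:0	0.00052	0.00052	0.0005094
1:Ins:C:1	0.00052	0.00052	0.0005094
1:Ins:C:2	0.00052	0.00052	0.0005094
1:Ins:C:3	0.00052	0.00052	0.0005094
1:Ins:C:4	0.00052	0.00052	0.0005094
1:Ins:C:5	0.0421217	0.00052	0.0005094
1:Ins:T:0	0.00052	0.00052	0.0005094
1:Ins:T:1	0.00052	0.00052	0.0005094
1:Ins:T:2	0.00052	0.00052	0.0005094
1:Ins:T:3	0.0837233	0.00052	0.0005094
1:Ins:T:4	0.2605304	0.00052	0.0005094
1:Ins:T:5	0.5725446	0.00052	0.0005094
2:Del:R:0	0.00052	0.00052	0.0005094
2:Del:R:1	0.00052	0.00052	0.0005094
2:Del:R:2	0.00052	0.00052	0.0005094
2:Del:R:3	0.00052	0.00052	0.0005094
2:Del:R:4	0.00052	0.00052	0.0005094
2:Del:R:5	0.00052	0.00052	0.0005094
3:Del:R:0	0.00052	0.00052	0.0616403
3:Del:R:1	0.00052	0.00052	0.0005094
3:Del:R:2	0.00052	0.00052	0.0005094
3:Del:R:3	0.00052	0.00052	0.0005094
3:Del:R:4	0.00052	0.00052	0.0005094
3:Del:R:5	0.00052	0.00052	0.0005094
4:Del:R:0	0.00052	0.00052	0.1023943
4:Del:R:1	0.00052	0.00052	0.0005094
4:Del:R:2	0.00052	0.00052	0.0005094
4:Del:R:3	0.00052	0.00052	0.0005094
4:Del:R:4	0.00052	0.00052	0.0005094
4:Del:R:5	0.00052	0.00052	0.0005094
5:Del:R:0	0.00052	0.00052	0.183904
5:Del:R:1	0.00052	0.00052	0.1431482
5:Del:R:2	0.00052	0.00052	0.0718288
5:Del:R:3	0.00052	0.00052	0.0005094
5:Del:R:4	0.00052	0.00052	0.0005094
5:Del:R:5	0.00052	0.00052	0.0005094
2:Ins:R:0	0.00052	0.00052	0.0005094
2:Ins:R:1	0.00052	0.00052	0.0005094
2:Ins:R:2	0.00052	0.00052	0.0005094
2:Ins:R:3	0.00052	0.00052	0.0005094
2:Ins:R:4	0.00052	0.00052	0.0005094
2:Ins:R:5	0.00052	0.00052	0.0005094
3:Ins:R:0	0.00052	0.00052	0.0005094
3:Ins:R:1	0.00052	0.00052	0.0005094
3:Ins:R:2	0.00052	0.00052	0.0005094
3:Ins:R:3	0.00052	0.00052	0.0005094
3:Ins:R:4	0.00052	0.00052	0.0005094
3:Ins:R:5	0.00052	0.00052	0.0005094
4:Ins:R:0	0.00052	0.00052	0.0005094
4:Ins:R:1	0.00052	0.00052	0.0005094
4:Ins:R:2	0.00052	0.00052	0.0005094
4:Ins:R:3	0.00052	0.00052	0.0005094
4:Ins:R:4	0.00052	0.00052	0.0005094
4:Ins:R:5	0.00052	0.00052	0.0005094
5:Ins:R:0	0.00052	0.00052	0.0005094
5:Ins:R:1	0.00052	0.00052	0.0005094
5:Ins:R:2	0.00052	0.00052	0.0005094
5:Ins:R:3	0.00052	0.00052	0.0005094
5:Ins:R:4	0.00052	0.00052	0.0005094
5:Ins:R:5	0.00052	0.00052	0.0005094
2:Del:M:1	0.00052	0.00052	0.0412634
3:Del:M:1	0.00052	0.00052	0.0514519
3:Del:M:2	0.00052	0.00052	0.0005094
4:Del:M:1	0.00052	0.00052	0.0616403
4:Del:M:2	0.00052	0.00052	0.0412634
4:Del:M:3	0.00052	0.00052	0.0005094
5:Del:M:1	0.00052	0.00052	0.0820173
5:Del:M:2	0.00052	0.00052	0.0718288
5:Del:M:3	0.00052	0.00052	0.0514519
5:Del:M:4	0.00052	0.00052	0.0005094
5:Del:M:5	0.00052	0.00052	0.0005094
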