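year,n,pct_men,pct_diabetes,pct_stroke,pct_ami,pct_cancer
2001,9676,49.2,3.4,1.7,2.6,4.4
2002,9744,48.3,3.2,2.1,3,3.9
2003,9877,49.3,3.6,2.3,2.9,4.6
2004,11117,48.9,3.9,2,3,5.4
2005,10378,48.9,4.4,2.4,3.1,6
2006,9607,49.0,4.4,2.4,2.8,5.5
2007,8741,48.3,4.8,2.5,2.9,5.9
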