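study_label,event_label,factor,outcome,odds_ratio,ci_low,ci_high
Liang 2001,1999 Chi-Chi Taiwan,age_over_65,death,1.1,1.0,1.1
Chou 2004,1999 Chi-Chi Taiwan,age_over_65,death,5.5,4.4,6.8
Dong 2012,2012 Sichuan,age_over_65,injury,4.6,1.8,11.5
Doocy 2013,2010 Haiti,age_over_65,injury,2.8,1.6,4.7
Shoaf 1998,California 1987-1994,age_over_65,injury,0.7,0.5,0.8
Peek-Asa 2003,1994 Northridge California,age_over_65,injury,2.9,1.2,7.4
Chou 2004,1999 Chi-Chi Taiwan,female,death,1.2,1.1,1.3
Shoaf 1998,California 1987-1994,female,injury,1.6,1.0,2.5
Peek-Asa 2003,1994 Northridge California,female,injury,2.4,1.2,5.1
Doocy 2009,2007 Ica Peru,female,injury,1.6,1.0,2.7
Chou 2004,1999 Chi-Chi Taiwan,disability,death,1.7,1.2,2.3
Osaki & Minowa 2001,1995 Great Hanshin Japan,disability,death,1.1,0.5,2.3
Chou 2004,1999 Chi-Chi Taiwan,low_ses,death,2.2,1.6,3.0
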