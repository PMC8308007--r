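element,rfd,csf,rda,ul,in_hi_list,in_cr_list,note
Li,2.0,NA,1000,NA,TRUE,FALSE,
Be,2.0,4300,NA,NA,TRUE,TRUE,
Mo,5.0,NA,45,2000,TRUE,FALSE,
Cd,1.0,380,NA,NA,TRUE,TRUE,
Sn,600.0,NA,NA,NA,TRUE,FALSE,
Ba,200.0,NA,NA,NA,TRUE,FALSE,
Pt,NA,NA,NA,NA,FALSE,FALSE,no established RfD
Au,NA,NA,NA,NA,FALSE,FALSE,no established RfD
Hg,0.3,NA,NA,NA,TRUE,FALSE,
Tl,0.01,NA,NA,NA,TRUE,FALSE,provisional RfD (PPRTV)
Pb,3.5,8.5,NA,NA,TRUE,TRUE,
Bi,NA,NA,NA,NA,FALSE,FALSE,no established RfD
Mg,NA,NA,6000,350000,FALSE,FALSE,no established RfD
Al,1000.0,NA,NA,NA,TRUE,FALSE,
Ti,NA,NA,NA,NA,FALSE,FALSE,no established RfD
V,5.04,NA,NA,18000,TRUE,FALSE,
Cr,3.0,500,NA,NA,FALSE,FALSE,RfD/CSF apply to Cr(VI) only; total Cr excluded from risk sums
Mn,140.0,NA,2300,11000,TRUE,FALSE,
Fe,700.0,NA,8000,45000,TRUE,FALSE,
Co,0.3,NA,NA,NA,TRUE,FALSE,
Cu,40.0,NA,900,10000,TRUE,FALSE,
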