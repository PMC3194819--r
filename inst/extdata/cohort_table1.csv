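id,gender,fr,febrile,ipi,onset,duration,surgery_age,side,genomic,mri,ipi_note
FS1,M,no,yes,4,4,9,13,right,TRUE,FALSE,
FS2,M,no,yes,1/8,7,18,25,left,TRUE,FALSE,
FS3,F,no,yes,1,8,11,19,right,FALSE,TRUE,
FS4,M,no,yes,4,4,26,30,right,TRUE,FALSE,
FS5,M,3rd,yes,0/6,15,14,29,left,FALSE,TRUE,
FS6,F,no,yes,2,14,5,19,right,TRUE,FALSE,
FS7,M,2nd,yes,2,2,37,39,left,TRUE,TRUE,
FS8,F,no,yes,0/6,2,55,57,right,TRUE,TRUE,
NFS9,F,no,no,7,7,21,28,left,TRUE,FALSE,
NFS10,M,no,no,1/6,5,27,32,left,TRUE,FALSE,d
NFS11,F,no,no,4,4,19,23,left,TRUE,FALSE,d
NFS12,F,no,no,13,13,29,42,left,TRUE,FALSE,
NFS13,M,no,no,0/9,8,20,28,left,FALSE,TRUE,d
NFS14,F,2nd,no,7,7,23,30,right,FALSE,TRUE,
NFS15,M,3rd,no,3,14,17,31,left,TRUE,TRUE,
NFS16,F,2nd,no,29,29,15,44,left,TRUE,TRUE,
NFS17,F,2nd,no,2,11,28,39,left,TRUE,TRUE,
NFS18,M,no,no,1,12,29,41,left,TRUE,FALSE,
NFS19,M,no,no,8,8,21,29,right,TRUE,TRUE,
NFS20,M,no,no,3,7,23,30,right,TRUE,TRUE,
NFS21,M,2nd,no,21,23,10,33,right,FALSE,TRUE,d
NFS22,F,2nd,no,18,18,7,25,left,TRUE,FALSE,
NFS23,F,3rd,no,13,13,42,55,right,TRUE,TRUE,
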