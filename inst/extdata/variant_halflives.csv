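name,mutations,halflife_dark,halflife_dark_se,halflife_light30,halflife_light30_se,ratio,ratio_se,ratio_significant,max_residue,degron_region,photoreceptor_unchanged
psd,,123,21,20,1,10.8,0.5,FALSE,NA,FALSE,TRUE
V19I,V19I,132,50,17,2,NA,NA,NA,19,FALSE,FALSE
K92R E132A E155G,K92R;E132A;E155G,102,41,12,0.4,21.7,2.5,TRUE,155,TRUE,FALSE
K92R E132A N148D E155G,K92R;E132A;N148D;E155G,103,26,10.5,0.3,12.2,1.1,FALSE,155,TRUE,FALSE
K92R E132A E139N N148D E155G,K92R;E132A;E139N;N148D;E155G,66,10,9.8,0.4,16.3,1.2,TRUE,155,TRUE,FALSE
K121M N128Y,K121M;N128Y,44,8,8.5,0.3,14.3,1.4,TRUE,128,FALSE,FALSE
K121M N128Y G138A,K121M;N128Y;G138A,92,28,13,1,21.7,4,TRUE,138,FALSE,FALSE
K121M N128Y N148E,K121M;N128Y;N148E,87,18,17,2,9.5,0.5,FALSE,148,TRUE,FALSE
E132D E139K,E132D;E139K,89,25,17,3,NA,NA,NA,139,FALSE,FALSE
E137D,E137D,165,43,24,4,NA,NA,NA,137,FALSE,FALSE
E137D E151D,E137D;E151D,79,25,21,3,NA,NA,NA,151,TRUE,FALSE
G138A,G138A,147,52,22,1,NA,NA,NA,138,FALSE,FALSE
G138A V142A R154G E155S,G138A;V142A;R154G;E155S,42,10,10.5,0.8,14.4,1.4,TRUE,155,TRUE,FALSE
G138A N148E,G138A;N148E,151,53,75,14,NA,NA,NA,148,TRUE,FALSE
G138A R154G E155S,G138A;R154G;E155S,27,4,7,0.3,NA,NA,NA,155,TRUE,FALSE
E139N,E139N,89,22,11,0.5,10.3,0.4,FALSE,139,FALSE,FALSE
V142G,V142G,31,4,19,3,NA,NA,NA,142,FALSE,FALSE
N148E,N148E,168,53,39,8,NA,NA,NA,148,TRUE,FALSE
N148E R154G E155S,N148E;R154G;E155S,91,35,13,1,13.5,0.7,TRUE,155,TRUE,FALSE
E151D,E151D,103,26,28,6,NA,NA,NA,151,TRUE,FALSE
R154G E155S,R154G;E155S,14,2,6.4,0.2,NA,NA,NA,155,TRUE,FALSE
dL156 dP157,dL156;dP157,187,45,52,9,NA,NA,NA,157,TRUE,FALSE
deg_ODC,cODC1-part,86,21,20,3,NA,NA,NA,NA,TRUE,TRUE
CACA,cODC1-part,87,21,20,3,NA,NA,NA,NA,TRUE,TRUE
CACACA,cODC1-part,66,13,16,1,NA,NA,NA,NA,TRUE,TRUE
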