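titer,symbol,description,size_bp,accession
low,BCL2L1,"BCL2-like, apoptotic regulator",702,BC019307
low,C20orf54,"solute carrier family 52, riboflavin transporter, member 3",1410,BC009750
low,C3orf1,translocase of inner mitochondrial membrane domain containing 1,858,BC012341
low,HIVEP2,"transcription factor, HIV type 1, enhancer binding protein 2",7402,NM_006734.3
low,MAP4K5,mitogen-activated protein kinase kinase kinase 5,2541,BC036013
low,MTCH1,mitochondrial carrier 1,927,BC000702
low,OPN5,"opsin 5, G-protein coupled receptor",1098,BC126194
low,PNMAL2,paraneoplastic MA antigen family-like 2,612,BC132839
low,SCAF8,"SR-related CTD-associated factor 8, RNA binding protein 16",4047,BC070071
high,AWAT2,acyl-CoA wax alcohol acyltransferase 2,1062,NM_001002254
high,FTSJ2,FTSJ homolog 2,741,BC121109
high,IQCE,IQ motif containing E,251,BC071858
high,KCTD2,potassium channel tetramerisation domain containing 2,853,NM_015353.1
high,RPL29,"ribosomal protein L29, cell surface heparin binding",522,BC008926
high,RPL8,ribosomal protein L8,774,BC000077
high,S100A6,S100 calcium binding protein A6,272,BC001431
high,TRPM8,"transient receptor potential cation channel, subfamily M, member 8",578,BC001135
high,TTC9,tetratricopeptide repeat domain 9,900,NM_015351.1
high,UQCRH,ubiquinol-cytochrome c reductase hinge protein,279,BC001426
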