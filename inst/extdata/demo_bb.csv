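bb_id,cycle,smiles,mw,n_unassigned_stereocenters,flags
S1,1,NCc1ccccc1,107.2,0,
S2,1,NCCc1ccc(F)cc1,139.2,0,
S3,1,NCC1CCCCC1,113.2,0,
A1,2,OC(=O)c1ccncc1,123.1,0,
A2,2,OC(=O)Cc1ccccc1,136.2,0,
A3,2,OC(=O)C1CCOC1,116.1,0,
A4,2,OC(=O)c1ccc(C)cc1,136.2,0,
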