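# Dopamine D3 receptor ligand fixtures (ChEMBL target 130 actives).
# mol1 is the reference compound of the worked example; mol2 is the first
# test molecule. The third test molecule of the original study was
# distributed only in that study's supplementary archive and is not
# available here; tools and tests operate on the molecules present.
CCCN(CCCCN1CCN(c2ccccc2OC)CC1)Cc1ccc2ccccc2c1	mol1
COc1cccc2cc(C(=O)NCCCCN3CCN(c4cccc5nccnc54)CC3)oc21	mol2
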