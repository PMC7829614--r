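row_id,classification,stratum,endpoint,x_ref,n_ref,x_alt,n_alt,printed_effect,printed_lo,printed_hi,printed_p
poor_hist_cdai50,histology,bcell_poor,cdai50,17,38,23,41,11,-11,33,0.31
poor_hist_cdai_mtr,histology,bcell_poor,cdai_mtr,9,38,19,41,23,2,43,0.035
poor_hist_cdai_lda,histology,bcell_poor,cdai_lda,11,38,19,41,17,-3,38,0.11
poor_hist_das28_esr_lda,histology,bcell_poor,das28_esr_lda,10,38,18,41,18,-4,38,0.10
poor_hist_das28_crp_lda,histology,bcell_poor,das28_crp_lda,12,38,19,41,15,-7,36,0.18
poor_hist_das28_esr_rem,histology,bcell_poor,das28_esr_rem,6,38,15,41,21,2,40,0.037
poor_hist_das28_crp_rem,histology,bcell_poor,das28_crp_rem,7,38,13,41,13,-6,32,0.17
poor_hist_eular_esr,histology,bcell_poor,eular_esr,25,38,36,41,22,4,40,0.031
poor_hist_eular_crp,histology,bcell_poor,eular_crp,22,38,32,41,20,0,40,0.054
poor_rna_cdai50,rnaseq,bcell_poor,cdai50,12,33,20,32,26,3,50,0.035
poor_rna_cdai_mtr,rnaseq,bcell_poor,cdai_mtr,4,33,16,32,38,17,59,0.0012
poor_rna_cdai_lda,rnaseq,bcell_poor,cdai_lda,5,33,16,32,35,14,56,0.0036
poor_rna_das28_esr_lda,rnaseq,bcell_poor,das28_esr_lda,6,33,17,32,35,13,57,0.0032
poor_rna_das28_crp_lda,rnaseq,bcell_poor,das28_crp_lda,7,33,16,32,29,7,51,0.015
poor_rna_das28_esr_rem,rnaseq,bcell_poor,das28_esr_rem,3,33,13,32,32,12,51,0.004
poor_rna_das28_crp_rem,rnaseq,bcell_poor,das28_crp_rem,4,33,10,32,19,0,39,0.076
poor_rna_eular_esr,rnaseq,bcell_poor,eular_esr,21,33,30,32,30,12,49,0.0053
poor_rna_eular_crp,rnaseq,bcell_poor,eular_crp,18,33,27,32,30,9,51,0.015
rich_hist_cdai50,histology,bcell_rich,cdai50,13,33,16,31,12,-12,37,0.33
rich_hist_cdai_mtr,histology,bcell_rich,cdai_mtr,5,33,11,31,20,-1,41,0.085
rich_hist_cdai_lda,histology,bcell_rich,cdai_lda,7,33,12,31,18,-5,40,0.13
rich_hist_das28_esr_lda,histology,bcell_rich,das28_esr_lda,8,33,13,31,18,-5,40,0.13
rich_hist_das28_crp_lda,histology,bcell_rich,das28_crp_lda,12,33,13,31,6,-18,30,0.65
rich_hist_das28_esr_rem,histology,bcell_rich,das28_esr_rem,2,33,11,31,29,11,48,0.0047
rich_hist_das28_crp_rem,histology,bcell_rich,das28_crp_rem,4,33,9,31,17,-3,36,0.12
rich_hist_eular_esr,histology,bcell_rich,eular_esr,25,33,27,31,11,-8,30,0.34
rich_hist_eular_crp,histology,bcell_rich,eular_crp,23,33,25,31,11,-10,32,0.31
rich_rna_cdai50,rnaseq,bcell_rich,cdai50,15,30,14,29,-2,-27,24,0.89
rich_rna_cdai_mtr,rnaseq,bcell_rich,cdai_mtr,7,30,9,29,8,-15,30,0.51
rich_rna_cdai_lda,rnaseq,bcell_rich,cdai_lda,10,30,10,29,1,-23,25,0.93
rich_rna_das28_esr_lda,rnaseq,bcell_rich,das28_esr_lda,9,30,10,29,5,-19,28,0.71
rich_rna_das28_crp_lda,rnaseq,bcell_rich,das28_crp_lda,14,30,11,29,-9,-34,16,0.50
rich_rna_das28_esr_rem,rnaseq,bcell_rich,das28_esr_rem,3,30,10,29,25,4,45,0.03
rich_rna_das28_crp_rem,rnaseq,bcell_rich,das28_crp_rem,4,30,8,29,14,-6,35,0.21
rich_rna_eular_esr,rnaseq,bcell_rich,eular_esr,24,30,24,29,3,-17,23,1.00
rich_rna_eular_crp,rnaseq,bcell_rich,eular_crp,23,30,23,29,3,-19,24,0.81
safety_any_ae,safety,safety,any_ae,76,108,94,117,10,-1,21,NA
safety_any_sae,safety,safety,any_sae,8,108,12,117,3,-5,10,NA
safety_sae_related,safety,safety,sae_related,4,108,8,117,3,-3,9,NA
safety_sae_unrelated,safety,safety,sae_unrelated,4,108,10,117,5,-1,11,NA
safety_sae_discontinuation,safety,safety,sae_discontinuation,2,108,3,117,1,-3,5,NA
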