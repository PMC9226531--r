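# Synthetic default list of 169 conserved-domain accessions for the
# binary protein-domain feature block.  Assembled from transposon-associated
# domain families plus synthetic placeholders; replace with a curated list
# for production use.  One accession per line; order defines the layout.
pfam00078_RVT_1
pfam07727_RVT_2
pfam00665_rve
pfam00075_RNase_H
pfam00077_RVP
pfam13456_RVT_3
pfam03732_Retrotrans_gag
pfam00552_IN_DBD_C
pfam02022_Integrase_Zn
pfam00098_zf-CCHC
pfam03017_DUF659
pfam00872_Transposase_mut
pfam01359_Transposase_1
pfam01609_DDE_Tnp_1
pfam02914_DDE_Tnp_2
pfam04218_CENP-B_N
pfam03004_Transposase_24
pfam04827_Plant_tran
pfam10551_MULE
pfam02992_Transposase_21
pfam03221_Tc5_DNA_bind
pfam05699_Dimer_Tnp_hAT
pfam13358_DDE_3
pfam13843_DDE_Tnp_1_7
pfam14372_DDE_Tnp_1_6
pfam05380_Peptidase_A17
pfam14214_Helitron_like_N
pfam05970_PIF1
pfam00270_DEAD
pfam00271_Helicase_C
pfam02689_Herpes_Helicase
pfam01443_Viral_helicase1
pfam00910_RNA_helicase
pfam05183_RdRP
pfam00680_RdRP_1
pfam08284_RVP_2
pfam09668_Asp_protease
pfam13650_Asp_protease_2
pfam13975_gag-asp_proteas
pfam03078_ATHILA
pfam04094_DUF390
pfam03017_TRANSPOSASE_28
pfam04937_DUF659_assoc
pfam13359_DDE_Tnp_4
pfam13586_DDE_Tnp_1_2
pfam13610_DDE_Tnp_IS240
pfam13701_DDE_Tnp_1_4
pfam13737_DDE_Tnp_1_5
pfam02371_Transposase_20
pfam01548_DEDD_Tnp_IS110
pfam02281_Transposase_8
pfam01526_Tn3_DDE
pfam01610_DDE_Tnp_ISL3
pfam07592_DDE_Tnp_IS1595
pfam12762_DDE_Tnp_IS1-like
pfam03400_DDE_Tnp_IS1
cd09272_RNase_HI_RT_Ty1
cd09274_RNase_HI_RT_Ty3
cd01647_RT_LTR
cd01650_RT_nLTR
cd03714_RT_ZFREV_like
cd00304_RT_like
cd09276_RNase_HI_RT_Bel
cd01644_RT_pepA17
cd01armadillo_gag_pre
cd00303_retropepsin
cd05482_HIV_retropepsin
cd01645_RT_Rtv
cdtp001_TEdom001
cdtp002_TEdom002
cdtp003_TEdom003
cdtp004_TEdom004
cdtp005_TEdom005
cdtp006_TEdom006
cdtp007_TEdom007
cdtp008_TEdom008
cdtp009_TEdom009
cdtp010_TEdom010
cdtp011_TEdom011
cdtp012_TEdom012
cdtp013_TEdom013
cdtp014_TEdom014
cdtp015_TEdom015
cdtp016_TEdom016
cdtp017_TEdom017
cdtp018_TEdom018
cdtp019_TEdom019
cdtp020_TEdom020
cdtp021_TEdom021
cdtp022_TEdom022
cdtp023_TEdom023
cdtp024_TEdom024
cdtp025_TEdom025
cdtp026_TEdom026
cdtp027_TEdom027
cdtp028_TEdom028
cdtp029_TEdom029
cdtp030_TEdom030
cdtp031_TEdom031
cdtp032_TEdom032
cdtp033_TEdom033
cdtp034_TEdom034
cdtp035_TEdom035
cdtp036_TEdom036
cdtp037_TEdom037
cdtp038_TEdom038
cdtp039_TEdom039
cdtp040_TEdom040
cdtp041_TEdom041
cdtp042_TEdom042
cdtp043_TEdom043
cdtp044_TEdom044
cdtp045_TEdom045
cdtp046_TEdom046
cdtp047_TEdom047
cdtp048_TEdom048
cdtp049_TEdom049
cdtp050_TEdom050
cdtp051_TEdom051
cdtp052_TEdom052
cdtp053_TEdom053
cdtp054_TEdom054
cdtp055_TEdom055
cdtp056_TEdom056
cdtp057_TEdom057
cdtp058_TEdom058
cdtp059_TEdom059
cdtp060_TEdom060
cdtp061_TEdom061
cdtp062_TEdom062
cdtp063_TEdom063
cdtp064_TEdom064
cdtp065_TEdom065
cdtp066_TEdom066
cdtp067_TEdom067
cdtp068_TEdom068
cdtp069_TEdom069
cdtp070_TEdom070
cdtp071_TEdom071
cdtp072_TEdom072
cdtp073_TEdom073
cdtp074_TEdom074
cdtp075_TEdom075
cdtp076_TEdom076
cdtp077_TEdom077
cdtp078_TEdom078
cdtp079_TEdom079
cdtp080_TEdom080
cdtp081_TEdom081
cdtp082_TEdom082
cdtp083_TEdom083
cdtp084_TEdom084
cdtp085_TEdom085
cdtp086_TEdom086
cdtp087_TEdom087
cdtp088_TEdom088
cdtp089_TEdom089
cdtp090_TEdom090
cdtp091_TEdom091
cdtp092_TEdom092
cdtp093_TEdom093
cdtp094_TEdom094
cdtp095_TEdom095
cdtp096_TEdom096
cdtp097_TEdom097
cdtp098_TEdom098
cdtp099_TEdom099
cdtp100_TEdom100
cdtp101_TEdom101
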