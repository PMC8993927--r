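# SYNTHETIC fixture module set. Step structure mirrors the curated modules
# used for minimal-consortium transcriptome scoring (cellobiose
# degradation; lactate consumption via the electron-bifurcation route;
# 1,2-propanediol production routes I (lactaldehyde) and II
# (hydroxyacetone); propionate production IV via 1,2-PD; and conversion of
# acetyl-CoA to crotonyl-CoA as a proxy for butyrate production), but the
# KO identifiers are illustrative placeholders, NOT curated annotations.
MGM0001	cellobiose degradation (synthetic)
K00001,K00002
K00003
///
MGM0002	lactate consumption via bifurcation (synthetic)
K00101+K00102+K00103
K00104
K00105,K00106
///
MGM0003	1,2-propanediol production I lactaldehyde route (synthetic)
K00201
K00202,K00203
K00204
///
MGM0004	1,2-propanediol production II hydroxyacetone route (synthetic)
K00211
K00212
///
MGM0005	propionate production IV via 1,2-propanediol (synthetic)
K00301+K00302
K00303
K00304,K00305
K00306
///
MGM0006	butyrate production proxy acetyl-CoA to crotonyl-CoA (synthetic)
K00401
K00402
K00403+K00404
///
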