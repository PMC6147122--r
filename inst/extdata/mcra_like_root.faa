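>mcra_like_root synthetic 550 aa root protein (generated, not from any database)
MYLNIPVQGDFGKWAPIFTTPMFKDVMPGACITAEGSSVPVSQESYSAMRTDCHENSKML
ALDTSVPFRSTMCTAVNDELMVALHAHGSRIGCLLVHVEVSGGQEGNQAPEFRVNVEGFA
KDKQSIFREYAILTTCQMGLRNIALRDNYIGLIGSTKTTKVSSSSSSSNKHTADTVPVEG
YLIEPLRKSVPAAPIEHVPEAVQVTSVAVGMFNRDGGNKQNVRQDTAVRGAIALGVMESL
AQTGDNKVAVTMAAAGTNKSYPAFWLGDDKLKCAYKKIFFGKLHFATTDDEQAGSTEWQA
GCWYLEALCDFDSVGEFLPPVNQDSESQEVELPADQLSIATSAAVVSHPGGLSGKGDDIY
ITGALDGKAADVVASMQNESSTCGAHCLATELAKSNVIRSRSLALLIRDWGSSDFGLVRS
YSDPNPLMLTVMSKFCRLADYFQGYNRSSMMDEDLEQKLQLVTEWACDKQGTPGPERGGL
DNSSKPNCRIWVITRQGKGYPRTKWLLTKPAFWFVRKETDPVTDADYLYESQFKTKCALE
SFVSRVITVV
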