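>collembola_coi_consensus IUPAC ambiguity consensus of public COI barcodes
NHNNNNNTNNNTNNWNHTNKSNNNNNKNNNNNSNHYNNYNGGNDYNDNNYTNARNNYNNNNNTNNSNNNN
RANNTNRSNVRNNYNRGNNNNNWNNTNRRNNRNGANCANVYNTANAAYRYNNYDRTNACNKCNCANGCNK
TYDYNATRATNTTYTTYRYDGTNAKNCCNNTHWTRVTHGGNGGNHTHGGNAANTKRHTNVTNCCNNTNAT
RVTNRRNKCNSCNGAYATNKCNTTNCCNCGNHTNANNAAYHTRAGNTTYTGRYTNYTNCCNCCNDSNHTN
NNNNTNNTNNBNNNNRGNDSNNYNDBNNANDNNGRNDNNGGNACNGGNTGRNNNNYNTAYCCNCCNNTNK
CNDVNNNNNYNDBNCANNNNGGNNBNDSNRTNGANNTNDNNATYTTYWSNYTNCANYYNRCNGGNRYNNS
NTMNATYYTNGGNGCNRTNARYTTYANNWSNWCNDBHDDNNAYATNNRNNNNNNNNNNNTNNNNTGRRAN
NDNNYNHBNYTNYTNNBNTGNDSNRTNHWHNTNACNDCNDYHYTNYTNBYNNYNDSNHTNCCNKTNNTNN
NNGGNGCNRTNWCNATRYTNNTNWYNGAYCGNAANNTNAANNCNDSNTTYTTYNNNCCNDSNGGNGGNGN
NGANYMNRWHYTNTWNCANCNYHWNNYY
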