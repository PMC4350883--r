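>synthref_I_NT synthetic reference domain, group I_NT
MSSTGWRKYGQKEVKNSPNALSVLTTSEGQCSVRKCAERGLDNPKAVITTFEGKHSHTHN
>synthref_I_CT synthetic reference domain, group I_CT
GSSVDWRKYGQKEVKNSENQLAVITTYEPRCTVRKCVERGLDDPKSVITTYEGKHNHTHQ
>synthref_IIc synthetic reference domain, group IIc
GASVDWRKYGQKEVKTSDSQLAVMTTYEPRCTVRKCIERGLDEPKSVITTYAGKHNHTHQ
>synthref_IId synthetic reference domain, group IId
AKRAGWRKYGQKDILDDGYRGNKYAQHKPRCSVYKCMRRGNPNPRSVVKTTSEDPSHSHE
>synthref_IIe synthetic reference domain, group IIe
TENLEWRKYGQKAPLNDGYAGNKSAQEQPRCPVKRCLQRGSEEPTMLITTYLGSHTHNHD
>synthref_ALGAL_SINGLE synthetic reference domain, group ALGAL_SINGLE
MALGTWRKYGQKSGNEVADILNRSEDGYKVCANRKCQDNSLPRAVITTSAGEHQTEHGHA
>synthref_DIPLOMONAD_TYPE synthetic reference domain, group DIPLOMONAD_TYPE
MEDLGWKKYGHKTGNEVADMLNKTEDGYRVCGNRKCQENSLVRAVITTSAGDHQTEHGHS
>synthref_IIa synthetic reference domain, group IIa
DSSAQWRKYGQKSDDGSLVAVKGNEHPKYECAEPKVCGSEDNSAQVQRKGVQGSTHEHLH
>synthref_IIb synthetic reference domain, group IIb
KQDGCWRKYGQKSDEGSLVAVKANEHPKYDCAEPRVCGSEDNTAQVQRKGVQGSAHEHLH
>synthref_III synthetic reference domain, group III
RDGFAWRKYGQKQTQVDHLEDDGYRVKLPRCGVRKCPVKRSPRAVVSTLEEDGSVQHVCK
>synthref_III_MOSS_VARIANT synthetic reference domain, group III_MOSS_VARIANT
RDSFAWKKYGNKQTQVDHLEDDGYRVKLPRCGVRKCPVKRSPRAVVSTLEEDGSIQHICK
>synthref_FUNGAL_TYPE synthetic reference domain, group FUNGAL_TYPE
MSQLEWKNNGNTQTSVDHLEDNGYKVKLSECSAGRKVCIRGSEYQRGPVKTTHNSVCAGT
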