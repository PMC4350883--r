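name	species	gene_model	seq_id	start	end	rw_family	notes
AtRWRKY52	Arabidopsis thaliana	AT5G45260	Chr5	18326203	18332609	NA	RRS1, ATWRKY52, SLH1
AtRWRKY16	Arabidopsis thaliana	AT5G45050	Chr5	18176914	18181805	NA	TTR1, ATWRKY16
AtRWRKY19	Arabidopsis thaliana	AT4G12020	Chr4	7201656	7208766	RW3	ATWRKY19, MAPKKK11
AlRWRKY1	Arabidopsis lyrata	AL915586	scaffold_8	2126189	2132181	NA	NA
AlRWRKY2	Arabidopsis lyrata	AL915663	scaffold_8	2768079	2773021	NA	NA
AlRWRKY3	Arabidopsis lyrata	AL915648	scaffold_8	2623905	2628796	NA	NA
SbRWRKY1	Sorguhum bicolor	SOBIC.002G104400	Chr02	12369911	12381876	NA	NA
SbRWRKY2	Sorguhum bicolor	Sobic.008G174100	Chr08	53517353	53522939	NA	NA
SbRWRKY3	Sorguhum bicolor	Sobic.002G168300	Chr02	52695615	52704484	NA	NA
CrRWRKY1	Capsella rubella	CARUBV10025744M	scaffold_8	1365382	1370221	NA	NA
CrRWRKY2	Capsella rubella	CARUBV10025742M	scaffold_8	1163667	1169265	NA	NA
OsjRWRKY1	Oryza sativa japonica	LOC_Os07g17230	Chr7	10149830	10159829	NA	FgenesH prediction different
OsiRWRKY1	Oryza sativa indica	BGIOSGA035675	Chromosome 11	21830082	21837218	NA	NA
OsjRWRKY2	Oryza sativa japonica	gi|108864659	Chr11	27783900	27793499	NA	Retrotransposon at 3 prime end
FvRWRKY1	Fragaria vesca	MRNA21370	LG7	18263740	18277966	NA	NA
FvRWRKY2	Fragaria vesca	MRNA13368	LG7	22236162	22242036	NA	NA
FvRWRKY3	Fragaria vesca	MRNA03900ALT	LG7	9804380	9813690	NA	NA
FvRWRKY4	Fragaria vesca	MRNA16678alt	LG6	802048	808355	NA	NA
AtaRWRKY1	Aegilops tauschii	R7VZB5	Scaffold219315	NA	NA	NA	no span printed
GmRWRKY1	Glycine Max	Glyma05g29921.1	Gm05	35364051	35374699	NA	NA
GrRWRKY1	Gossypium raimondii	Gorai.008G201000	Chr08	48587929	48599304	RW7	WRKY domains truncated
GrRWRKY2	Gossypium raimondii	Gorai.008G200800	Chr08	48660141	48668419	RW7	NA
TcRWRKY1	Theobroma cacao	Thecc1EG006109	scaffold_2	820964	828678	NA	NA
TcRWRKY2	Theobroma cacao	Thecc1EG006103	scaffold_2	805474	814178	NA	NA
TcRWRKY3	Theobroma cacao	Thecc1EG006116t1	scaffold_2	845249	851848	NA	NA
HvRWRKY1	Hordeum vulgare	MLOC_74974.5	Chr5	483720745	483727238	NA	NA
SiRWRKY1	Setaria italica	Si028710m.g	scaffold_2	26415481	26421105	NA	NA
PvRWRKY1	Panicum virgatum	Pavir.J20878	contig22731	NA	NA	NA	sg0.contig22731/9-CL19939Contig1
FvRWRKY5	Fragaria vesca	MRNA21370	LG7	18263740	18277966	NA	Tandem repeat with FvRWRKY1
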