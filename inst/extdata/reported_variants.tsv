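gene_id	Variant	Description	Exon	annovar_nt	annovar_aa	mature_nt	mature_aa	Domain	carrier_count	cohort_size	pct_printed
FCGR1	chr1:101378924:A>G	nonsynonymous SNP	3	c.T134C	p.V45A	T83C	V28A	Extracellular	52	206	25.2
FCGR1	chr1:101378806:C>G	nonsynonymous SNP	3	c.G252C	p.R84S	G201C	R67S	Extracellular	36	206	17.5
FCGR1	chr1:101378828:A>G	nonsynonymous SNP	3	c.T230C	p.V77A	T179C	V60A	Extracellular	28	206	13.6
FCGR1	chr1:101378934:G>C	nonsynonymous SNP	3	c.C124G	p.Q42E	C73G	Q25E	Extracellular	10	206	4.8
FCGR1	chr1:101374528:G>A	nonsynonymous SNP	4	c.C457T	p.L153F	C406T	L136F	Extracellular	7	206	3.4
FCGR1	chr1:101378991:>T	fs insertion	3	c.66dupA	p.V23fs	15dupA	V6fs	Extracellular	6	206	2.9
FCGR1	chr1:101373136:C>T	synonymous SNP	5	c.G603A	p.P201P	G552A	P184P	Extracellular	5	206	2.4
FCGR1	chr1:101378972:G>A	nonsynonymous SNP	3	c.C86T	p.P29L	C35T	P12L	Extracellular	5	206	2.4
FCGR2A	chr1:89419258:>ATC	non-fs insertion	7	c.894_895insGAT	p.R299delinsDR	789_790insGAT	R264delinsDR	Cytoplasmic	140	206	68
FCGR2A	chr1:89431476:C>T	synonymous SNP	3	c.G114A	p.P38P	G9A	P3P	Extracellular	24	206	11.6
FCGR2A	chr1:89431321:A>C	nonsynonymous SNP	3	c.T269G	p.M90R	T164G	M55R	Extracellular	24	206	11.6
FCGR2A	chr1:89431407:A>G	synonymous SNP	3	c.T183C	p.C61C	T78C	C26C	Extracellular	23	206	11.1
FCGR2A	chr1:89427299:G>T	nonsynonymous SNP	4	c.C489A	p.N163K	C384A	N128K	Extracellular	23	206	11.1
FCGR2A	chr1:89431374:G>A	synonymous SNP	3	c.C216T	p.T72T	C111T	T37T	Extracellular	23	206	11.1
FCGR2A	chr1:89419246:T>G	nonsynonymous SNP	7	c.A907C	p.M303L	A802C	M268L	Cytoplasmic	22	206	10.7
FCGR2A	chr1:89427309:T>A	nonsynonymous SNP	4	c.A479T	p.K160I	A374T	K125I	Extracellular	16	206	7.8
FCGR2A	chr1:89427264:T>C	nonsynonymous SNP	4	c.A524G	p.Q175R	A419G	Q140R	Extracellular	13	206	6.3
FCGR2A	chr1:89427254:G>A	synonymous SNP	4	c.C534T	p.H178H	C429T	H143H	Extracellular	8	206	3.9
FCGR2A	chr1:89427291:T>G	nonsynonymous SNP	4	c.A497C	p.H166P	A392C	H131P	Extracellular	5	206	2.4
FCGR2A	chr1:89427286:T>C	nonsynonymous SNP	4	c.A502G	p.N168D	A397G	N133D	Extracellular	5	206	2.4
FCGR2A	chr1:89419298:G>A	synonymous SNP	7	c.C855T	p.G285G	C750T	G250G	Cytoplasmic	5	206	2.4
FCGR2B	chr1:89331119:T>C	nonsynonymous SNP	4	c.A532G	p.N178D	A397G	N133D	Extracellular	43	206	20.9
FCGR2B	chr1:89331140:A>C	nonsynonymous SNP	4	c.T511G	p.S171A	T376G	S126A	Extracellular	30	206	14.6
FCGR2B	chr1:89331111:G>A	synonymous SNP	4	c.C540T	p.N180N	C405T	N135N	Extracellular	29	206	14.1
FCGR2B	chr1:89326856:A>G	synonymous SNP	7	c.T846C	p.D282D	T711C	D237D	Extracellular	17	206	8.2
FCGR2B	chr1:89331097:T>C	nonsynonymous SNP	4	c.A554G	p.Q185R	A419G	Q140R	Extracellular	12	206	5.8
FCGR2B	chr1:89331161:T>C	nonsynonymous SNP	4	c.A490G	p.T164A	A355G	T119A	Extracellular	9	206	4.4
FCGR2B	chr1:89331142:A>T	nonsynonymous SNP	4	c.T509A	p.I170K	T374A	I125K	Extracellular	6	206	2.9
FCGR2B	chr1:89331246:G>A	synonymous SNP	4	c.C405T	p.L135L	C270T	L90L	Extracellular	6	206	2.9
FCGR2B	chr1:89331024:A>G	synonymous SNP	4	c.T627C	p.P209P	T492C	P164P	Extracellular	5	206	2.4
FCGR3	chr1:89392794:G>A	nonsynonymous SNP	5	c.G805A	p.V269I	G643A	V215I	Cytoplasmic	139	206	67.5
FCGR3	chr1:89392782:G>A	nonsynonymous SNP	5	c.G793A	p.V265M	G631A	V211M	Cytoplasmic	138	206	67
FCGR3	chr1:89387252:G>A	synonymous SNP	3	c.G411A	p.Q137Q	G249A	Q83Q	Extracellular	35	206	17
FCGR3	chr1:89390827:A>G	nonsynonymous SNP	4	c.A634G	p.I212V	A472G	I158V	Extracellular	16	206	7.8
FCGR3	chr1:89392727:T>C	synonymous SNP	5	c.T738C	p.S246S	T576C	S192S	Extracellular	8	206	3.9
FCGR3	chr1:89390721:G>A	synonymous SNP	4	c.G528A	p.T176T	G366A	T122T	Extracellular	8	206	3.9
FCGR3	chr1:89387025:G>T	nonsynonymous SNP	3	c.G184T	p.A61S	G22T	A8S	Extracellular	6	206	2.9
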