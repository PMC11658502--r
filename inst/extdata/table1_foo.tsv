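prey	TW.O	TW.M	TW.J	TW.S	TW.D	SL.O	SL.M	SL.J	SL.S	SL.D	EL.O	EL.M	EL.J	TF.O	TF.M	TF.J	TF.S	TF.D	RF.O	RF.M	RF.J	RF.S	RF.D	PC.O	PC.S	PC.D
Domestic Yak	11.0	15.9	14.1	0.0	5.7	4.3	7.7	0.0	0.0	0.0	0.0	0.0	0.0	2.9	3.4	5.6	0.0	0.0	4.2	8.0	5.9	3.0	3.3	0.0	0.0	0.0
Domestic Camel	0.3	0.0	0.0	2.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0
Domestic Goat	3.2	3.7	4.0	0.0	3.8	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.6	0.0	0.0	0.0	1.7	0.0	0.0	0.0
Domestic Sheep	3.2	7.3	3.4	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0
Blue Sheep	39.2	57.3	44.1	5.0	34.0	59.6	73.1	100.0	28.6	60.0	28.6	33.3	25.0	4.3	3.4	11.1	0.0	0.0	10.1	20.0	17.6	4.5	10.0	0.0	0.0	0.0
White-lipped Deer	0.3	0.0	0.0	1.7	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0
Tibetan Fox	1.9	2.4	0.0	1.7	7.5	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0
Red Fox	3.8	0.0	1.1	0.0	22.6	2.1	0.0	0.0	0.0	20.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0
Himalayan Marmot	13.7	0.0	15.3	33.3	7.5	4.3	0.0	0.0	14.3	0.0	14.3	0.0	25.0	4.3	3.4	5.6	0.0	5.6	4.8	0.0	17.6	7.6	0.0	0.0	0.0	0.0
Woolly Hare	1.6	0.0	1.7	1.7	3.8	0.0	0.0	0.0	0.0	0.0	14.3	33.3	0.0	0.0	0.0	0.0	0.0	0.0	3.0	0.0	5.9	1.5	5.0	0.0	0.0	0.0
Zokor	0.3	0.0	0.0	0.0	1.9	2.1	0.0	0.0	7.1	0.0	0.0	0.0	0.0	1.4	0.0	0.0	0.0	5.6	0.6	0.0	0.0	1.5	0.0	0.0	0.0	0.0
Mountain Weasel	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0
Pika	11.8	9.8	14.1	8.3	11.3	12.8	7.7	0.0	21.4	20.0	42.9	33.3	50.0	79.7	79.3	77.8	50.0	88.9	53.6	48.0	52.9	53.0	56.7	90.0	80.0	100.0
Long-tailed Dwarf Hamster	0.3	0.0	0.0	1.7	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	2.4	0.0	0.0	0.0	6.7	0.0	0.0	0.0
Vole Species	1.3	2.4	1.7	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	2.9	6.9	0.0	0.0	0.0	9.5	24.0	0.0	4.5	11.7	0.0	0.0	0.0
Common Shrew	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.6	0.0	0.0	1.5	0.0	0.0	0.0	0.0
Birds of Prey	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	1.4	3.4	0.0	0.0	0.0	0.6	0.0	0.0	1.5	0.0	0.0	0.0	0.0
Perching Birds	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	1.4	0.0	0.0	25.0	0.0	1.8	0.0	0.0	3.0	1.7	0.0	0.0	0.0
Ground Feeding Birds	1.1	1.2	0.0	3.3	1.9	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	0.0	4.2	0.0	0.0	7.6	3.3	0.0	0.0	0.0
Undetermined	7.3	0.0	0.6	41.0	0.0	14.9	11.5	0.0	28.6	0.0	0.0	0.0	0.0	1.4	0.0	0.0	25.0	0.0	4.2	0.0	0.0	10.6	0.0	10.0	20.0	0.0
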