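category	mirna	n_curated	n_de_targets
up	miR-429-3p	438	39
up	miR-200a-3p	394	25
up	miR-200b-3p	410	25
up	miR-200c-3p	382	26
up	miR-182-5p	379	18
up	miR-326-3p	175	16
up	miR-199a-5p	249	24
up	miR-673-3p	0	0
up	miR-337-3p	36	2
up	miR-337-5p	0	0
up	miR-540-3p	0	0
up	miR-431-5p	178	5
up	miR-127-3p	39	1
up	miR-127-5p	1	0
up	miR-434-3p	7	0
up	miR-434-5p	23	2
up	miR-136-3p	0	0
up	miR-136-5p	501	24
up	miR-379-5p	138	6
up	miR-379-3p	0	0
up	miR-411-3p	26	2
up	miR-411-5p	140	15
up	miR-299a-5p	18	1
up	miR-329-3p	329	5
up	miR-494-3p	427	26
up	miR-1193-3p	0	0
up	miR-543-3p	480	36
up	miR-495-3p	644	40
up	miR-376c-3p	337	18
up	miR-376b-3p	227	10
up	miR-376b-5p	0	0
up	miR-376a-3p	11	1
up	miR-300-3p	40	6
up	miR-381-3p	606	45
up	miR-382-5p	296	20
up	miR-382-3p	1	0
up	miR-134-5p	203	14
up	miR-485-5p	140	9
up	miR-485-3p	0	0
up	miR-154-3p	0	0
up	miR-154-5p	226	11
up	miR-496a-3p	218	13
up	miR-541-5p	298	20
up	miR-409-5p	0	0
up	miR-409-3p	29	2
up	miR-369-3p	0	0
up	miR-369-5p	0	0
up	miR-410-3p	524	29
down	miR-455-3p	3	0
down	miR-455-5p	0	0
down	miR-31-3p	0	0
down	miR-31-5p	334	36
down	miR-93-5p	705	83
down	miR-339-3p	0	0
down	miR-335-5p	223	19
down	miR-486b-5p	28	2
down	miR-144-3p	709	72
down	miR-451a	108	31
down	miR-345-5p	18	5
down	miR-17-5p	992	115
down	miR-19a-3p	602	62
down	miR-484	0	0
down	miR-802-5p	0	0
down	miR-145a-5p	262	26
down	miR-322-5p	817	80
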