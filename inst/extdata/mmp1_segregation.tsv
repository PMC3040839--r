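individual_id	genotype	class
donor01	hom_1G	low
donor02	hom_1G	low
donor03	hom_1G	low
donor04	hom_1G	low
donor05	hom_1G	low
donor06	hom_1G	low
donor07	hom_1G	low
donor08	hom_1G	low
donor09	hom_1G	low
donor10	hom_1G	low
donor11	hom_1G	low
donor12	hom_2G	high
donor13	hom_2G	high
donor14	hom_2G	high
donor15	hom_2G	high
donor16	hom_2G	high
donor17	hom_2G	low
donor18	het	high
donor19	het	high
donor20	het	high
donor21	het	high
donor22	het	high
donor23	het	high
donor24	het	high
donor25	het	high
donor26	het	high
donor27	het	high
donor28	het	high
donor29	het	high
donor30	het	high
donor31	het	high
donor32	het	high
donor33	het	high
donor34	het	high
donor35	het	high
donor36	het	high
donor37	het	high
donor38	het	high
donor39	het	high
donor40	het	high
donor41	het	high
donor42	het	high
donor43	het	high
donor44	het	high
donor45	het	high
donor46	het	high
donor47	het	high
donor48	het	high
donor49	het	high
donor50	het	high
donor51	het	high
donor52	het	high
donor53	het	high
donor54	het	high
donor55	het	high
donor56	het	high
donor57	het	high
donor58	het	high
donor59	het	high
donor60	het	high
donor61	het	high
donor62	het	high
donor63	het	high
donor64	het	high
donor65	het	high
donor66	het	high
donor67	het	high
donor68	het	high
donor69	het	high
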