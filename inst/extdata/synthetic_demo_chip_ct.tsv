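sample_id	group	antibody	region	ct_ip	ct_input	input_fraction
A01	A	ZEB1	promoter	29.9028852382708	29.8466407929277	0.1
A02	A	ZEB1	promoter	29.5961666059058	29.8367083311663	0.1
A03	A	ZEB1	promoter	30.0647257010002	29.9716929628154	0.1
A04	A	ZEB1	promoter	30.0148822711893	29.9444789940342	0.1
A05	A	ZEB1	promoter	29.9692901362694	30.0872613796857	0.1
B01	B	ZEB1	promoter	31.9138335980765	29.7626254950066	0.1
B02	B	ZEB1	promoter	32.5109790524922	30.2383973815167	0.1
B03	B	ZEB1	promoter	32.6261577404494	29.9963619314203	0.1
B04	B	ZEB1	promoter	32.3815267120868	29.9503830804661	0.1
B05	B	ZEB1	promoter	32.5623330868759	29.927412621847	0.1
A01	A	ZEB2	promoter	30.3054481452529	30.2555141096535	0.1
A02	A	ZEB2	promoter	29.5137368445804	29.9062205706041	0.1
A03	A	ZEB2	promoter	29.8523987757653	30.014210820339	0.1
A04	A	ZEB2	promoter	29.8470552924861	29.9467923100495	0.1
A05	A	ZEB2	promoter	30.4300757928161	30.3690514390553	0.1
B01	B	ZEB2	promoter	32.0961967149971	29.8321100685094	0.1
B02	B	ZEB2	promoter	32.5979813233175	29.9845103882728	0.1
B03	B	ZEB2	promoter	31.9731380863533	29.4764588947465	0.1
B04	B	ZEB2	promoter	32.3089136917252	30.1775768051632	0.1
B05	B	ZEB2	promoter	32.1740947104351	29.8585017107405	0.1
A01	A	IGG	promoter	36.0180699526291	30.3513985880655	0.1
A02	A	IGG	promoter	35.4695746422458	30.0364504286405	0.1
A03	A	IGG	promoter	35.6216782698264	29.9466222509573	0.1
A04	A	IGG	promoter	36.0892193587655	30.1852843262495	0.1
A05	A	IGG	promoter	35.2740125253154	29.8613336245614	0.1
B01	B	IGG	promoter	36.2234625743498	30.5363980139419	0.1
B02	B	IGG	promoter	35.8492567238756	30.0445048960312	0.1
B03	B	IGG	promoter	35.3560985615813	29.8586655176881	0.1
B04	B	IGG	promoter	35.403679215045	30.083442649154	0.1
B05	B	IGG	promoter	35.8855813995664	30.073911355631	0.1
A01	A	ZEB1	control	35.3908157305881	29.8172471301173	0.1
A02	A	ZEB1	control	35.4372163619184	29.9366170509373	0.1
A03	A	ZEB1	control	35.6656096602618	30.2098118410612	0.1
A04	A	ZEB1	control	35.8235116929484	30.0336223613071	0.1
A05	A	ZEB1	control	35.5625701361744	30.0062880423007	0.1
B01	B	ZEB1	control	35.3919136619749	29.7979338921251	0.1
B02	B	ZEB1	control	35.5859923089523	30.0765503064765	0.1
B03	B	ZEB1	control	35.6401196979958	29.8360606948926	0.1
B04	B	ZEB1	control	35.41842602258	30.07234221886	0.1
B05	B	ZEB1	control	35.7533327816337	30.0186742726299	0.1
A01	A	ZEB2	control	35.6664210334418	29.8383087311735	0.1
A02	A	ZEB2	control	35.1770967052438	29.5961236611203	0.1
A03	A	ZEB2	control	35.6285743515109	29.8522551855139	0.1
A04	A	ZEB2	control	35.4930413247249	30.0765773121716	0.1
A05	A	ZEB2	control	36.1152287224602	30.3461727335149	0.1
B01	B	ZEB2	control	35.449010901053	29.9593836098551	0.1
B02	B	ZEB2	control	35.4579653801947	29.8007205304951	0.1
B03	B	ZEB2	control	35.0482400281485	29.7386927410757	0.1
B04	B	ZEB2	control	35.2686129825542	29.8004336792199	0.1
B05	B	ZEB2	control	35.5978363587762	29.8869942547234	0.1
A01	A	IGG	control	36.0254733062005	30.3504115671736	0.1
A02	A	IGG	control	35.5688305088255	29.8904457296813	0.1
A03	A	IGG	control	35.5830254761423	29.8282948584044	0.1
A04	A	IGG	control	35.6385429225826	30.0098589066408	0.1
A05	A	IGG	control	35.7863490609146	29.9599911036388	0.1
B01	B	IGG	control	35.0424822838654	29.779209110199	0.1
B02	B	IGG	control	35.4519590365697	30.04811760763	0.1
B03	B	IGG	control	35.6178078785317	30.0762227231407	0.1
B04	B	IGG	control	36.2043916641797	30.4460917899169	0.1
B05	B	IGG	control	35.9198348181821	30.2398404784102	0.1
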