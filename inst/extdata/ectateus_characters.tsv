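char	body_region	description	states
1	head	Antenna robustness relative to pronotum	0 slender, longer than pronotum; 1 robust, shorter than pronotum
2	head	Antennomeres 7-11 proportions	0 widened (wider than long); 1 elongated (longer than wide)
3	head	Circular depressions on lateral clypeus and genae	0 absent; 1 present
4	head	Fronto-clypeal suture	0 fine; 1 coarse, clearly visible
5	head	Indentation between frons and clypeus at lateral edge	0 shallow; 1 deep
6	head	Anterior tentorial pit	0 shallow; 1 deep, clearly visible
7	head	Anterior part of mentum	0 not elongated; 1 elongated
8	prothorax	Anterior pronotal angles	0 straight; 1 curved outwards
9	prothorax	Lateral pronotal sides	0 rounded; 1 sinusoidal
10	prothorax	Pronotum widest point	0 at the middle; 1 at the base
11	prothorax	Pronotal margins	0 not erected upwards; 1 strongly erected upwards
12	prothorax	Prothorax width to pronotal disc height ratio	0 below 5; 1 above 6
13	prothorax	Apophyseal depressions	0 absent; 1 trapezoidal; 2 rounded
14	prothorax	Pronotal base width vs elytral base	0 same width; 1 narrower
15	prothorax	Posterior pronotal angles	0 not protruding towards elytra; 1 strongly protruding
16	prothorax	Punctures on pronotal disc	0 fine, widely spaced; 1 coarse, densely spaced
17	prothorax	Intercoxal process of prosternum profile	0 flat or dented; 1 bellied
18	prothorax	Intercoxal process of prosternum apex	0 not widened; 1 strongly widened
19	mesothorax	Scutellum	0 at elytral level; 1 impressed
20	mesothorax	Elytral surface	0 dull; 1 shiny
21	mesothorax	Elytral intervals with transverse sculpture	0 no; 1 yes
22	mesothorax	Elytral intervals convexity	0 flat; 1 strongly convex
23	mesothorax	Elytral striae	0 impressed on whole length, fine punctures; 1 impressed mainly near conspicuous punctures
24	mesothorax	Margins of elytra in basal part	0 rounded; 1 subparallel, humeri slightly protruding
25	metathorax	Metaventrite longitudinal depression	0 absent; 1 coarse depression present
26	abdomen	Fifth abdominal ventrite width	0 relatively narrow; 1 strongly widened
27	abdomen	Fifth abdominal ventrite border	0 unbordered; 1 bordered
28	legs	Male protarsi widened	0 no; 1 yes
29	legs	Female protarsi widened	0 no; 1 yes
30	legs	Male profemora proportions	0 relatively wide (L/W 3.2-3.6); 1 relatively slender (L/W 4.0-5.6)
31	legs	Denticle at apex of inner face of male mesotibia	0 small or absent; 1 large
32	genitalia	Penis width	0 not wide; 1 at least 4x wider than clavae
33	genitalia	Clavae shape	0 straight; 1 curved, hook-shaped
34	genitalia	Clavae length vs parameres	0 short, less than half; 1 long, more than half
35	genitalia	Parameres strongly extended apically	0 no; 1 yes
36	genitalia	Parameres narrowest at half length	0 no; 1 yes
37	genitalia	Apex of parameres	0 not fused; 1 fused, not emarginated; 2 fused, emarginated at apex
38	genitalia	Bursa copulatrix	0 without additional sacs; 1 with 2 additional sacs
39	genitalia	Paraproct vs coxites length	0 not longer; 1 longer
40	other	Body size	0 more than 10.0 mm; 1 less than 9.0 mm
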