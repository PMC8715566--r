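# icfkit seed registry: the nine Activities & Participation chapters, the five
# Environmental Factors chapters, two example blocks, and the categories used
# by the bundled case-study fixtures. Columns: code, title, kind, parent.
code	title	kind	parent
d1	Learning and applying knowledge	chapter	NA
d2	General tasks and demands	chapter	NA
d3	Communication	chapter	NA
d4	Mobility	chapter	NA
d5	Self-care	chapter	NA
d6	Domestic life	chapter	NA
d7	Interpersonal interactions and relationships	chapter	NA
d8	Major life areas	chapter	NA
d9	Community, social and civic life	chapter	NA
e1	Products and technology	chapter	NA
e2	Natural environment and human-made changes to environment	chapter	NA
e3	Support and relationships	chapter	NA
e4	Attitudes	chapter	NA
e5	Services, systems and policies	chapter	NA
d160-d179	Applying knowledge	block	d1
d330-d349	Communicating - producing	block	d3
d170	Writing	category	d160-d179
d330	Speaking	category	d330-d349
d345	Writing messages	category	d330-d349
d410	Changing basic body positions	category	d4
d415	Maintaining a body position	category	d4
d4153	Maintaining a sitting position	category	d415
d4154	Maintaining a standing position	category	d415
d420	Transferring oneself	category	d4
d4200	Transferring oneself while sitting	category	d420
d430	Lifting and carrying objects	category	d4
d4300	Lifting	category	d430
d440	Fine hand use	category	d4
d445	Hand and arm use	category	d4
d465	Moving around using equipment	category	d4
d720	Complex interpersonal interactions	category	d7
d7202	Regulating behaviours within interactions	category	d720
d850	Remunerative employment	category	d8
e110	Products or substances for personal consumption	category	e1
e1101	Drugs	category	e110
e115	Products and technology for personal use in daily living	category	e1
e1151	Assistive products for personal mobility	category	e115
e155	Design, construction of building for private use	category	e1
e580	Health services, systems and policies	category	e5
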