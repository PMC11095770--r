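a001	e001	t001
a001	e003	t002
a002	e001	t001
a002	e002	t001
a003	e001	t002
a003	e003	t002
a004	e003	t002
a004	e002	t001
a005	e002	t002
a005	e003	t001
a006	e003	t003
a006	e001	t001
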