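pw1	fixture pathway	M01	M02	M03
pw2	fixture pathway	M01	M02	M03	M04	M05
pw3	fixture pathway	M01	M02	M03	M04	M05	M06	M07	M08
pw4	fixture pathway	M01	M02	M03	M04	M05	M06	M07	M08	M09	M10
pw5	fixture pathway	M01	M02	M03	M04	M05	M06	M07	M08	M09	M10	M11	M12
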