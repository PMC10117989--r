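psd_id,group,area_1e4nm2,thickness_nm,volume_1e4nm3
PSD1,control,10.71,154.6,1205
PSD2,control,16.17,161.4,807.5
PSD3,control,8.125,99.29,408.3
PSD4,control,28.85,110.3,600.7
PSD5,control,33.23,141.7,1737
PSD6,control,8.836,192.4,428.3
PSD1,sonicated,14.99,124.0,730.5
PSD2,sonicated,10.64,142.5,675.9
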