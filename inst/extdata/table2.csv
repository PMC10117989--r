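psd_id,group,module_id,volume_1e4nm3,size_nm
PSD1,control,1,33.27,132.31
PSD1,control,2,28.42,141.48
PSD1,control,3,18.16,114.232
PSD1,control,4,11.64,107.944
PSD1,control,5,16.76,109.516
PSD1,control,6,8.831,103.49
PSD1,control,7,6.007,105.586
PSD1,control,8,7.733,103.752
PSD2,control,1,52.34,106.634
PSD3,control,1,26.44,128.118
PSD3,control,2,9.694,93.272
PSD3,control,3,14.44,114.232
PSD3,control,4,10.97,117.638
PSD3,control,5,14.12,101.918
PSD4,control,1,18.34,120.52
PSD4,control,2,19.24,127.594
PSD1,sonicated,1,12.38,121.24
PSD1,sonicated,2,10.14,105
PSD2,sonicated,1,46.32,168.84
PSD2,sonicated,2,43.25,139.44
PSD2,sonicated,3,28.98,153.44
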