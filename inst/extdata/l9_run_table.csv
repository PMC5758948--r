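run_id,A_level,B_level,C_level,D_level,designation,orww_pct,temp_c,sonication_min,ts_pct,bgp_mean_ml_gvs,bgp_sd,bmp_mean_ml_gvs,bmp_sd,cods_mean_pct,cods_sd,snr_bgp_db,snr_bmp_db,snr_cods_db
1,1,1,1,1,A1B1C1D1,33,36,15,6,167.39,16.92,79.58,8.85,68.81,11.96,44.34,37.87,36.35
2,2,1,2,3,A2B1C2D3,44,36,30,18,240.01,5.25,124.09,6.84,69.85,13.16,47.60,41.83,36.40
3,2,2,3,1,A2B2C3D1,44,46,0,6,270.99,7.87,126.78,6.74,57.69,3.19,48.65,42.03,35.18
4,1,2,2,2,A1B2C2D2,33,46,30,11,136.28,3.18,67.76,9.21,-123.25,12.96,42.68,36.35,33.26
5,3,3,2,1,A3B3C2D1,55,56,30,6,104.02,5.83,61.64,5.35,-81.33,25.72,40.30,35.70,35.89
6,3,2,1,3,A3B2C1D3,55,46,15,18,86.54,10.15,41.11,6.77,80.57,0.40,38.56,31.86,38.12
7,1,3,3,3,A1B3C3D3,33,56,0,18,17.07,0.92,9.34,1.73,-263.42,0.00,24.60,18.96,48.41
8,2,3,1,2,A2B3C1D2,44,56,15,11,25.55,1.51,13.62,3.16,-91.95,29.89,28.10,21.81,37.81
9,3,1,3,2,A3B1C3D2,55,36,0,11,140.11,0.31,69.98,4.79,77.44,4.03,42.93,36.83,37.75
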