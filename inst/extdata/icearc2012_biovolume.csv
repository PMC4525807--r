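block,method,ICE-1,ICE-2,ICE-3,ICE-5,ICE-6,ICE-7,ICE-8,ICE-9,Mean
volume_ml_m2,global_mean,0.4,2.1,0.02,0.03,0.04,10.4,1.1,0.03,1.8
volume_ml_m2,global_median,0.2,0.5,0.005,0.01,0.01,4.8,0.5,0.01,0.7
volume_ml_m2,gridded_mean,2.5,6.0,0.7,0.3,0.4,16.8,6.5,0.3,4.2
volume_ml_m2,gridded_median,0.9,1.4,0.5,0.1,0.2,21.9,4.1,0.3,3.7
volume_ml_m2,raster_cells,5.2,16.3,4.7,1.6,3.0,38.6,6.9,1.7,9.7
volume_ml_m2,aggregate_list,2.2,20.4,0.2,0.5,0.7,52.5,6.9,0.4,10.5
carbon_mg_m2,global_mean,0.2,0.8,0.01,0.01,0.02,4.0,0.4,0.01,0.7
carbon_mg_m2,global_median,0.1,0.2,0.005,0.005,0.005,1.9,0.2,0.005,0.3
carbon_mg_m2,gridded_mean,1.0,2.3,0.3,0.1,0.1,6.5,2.5,0.1,1.6
carbon_mg_m2,gridded_median,0.4,0.5,0.2,0.03,0.07,8.5,1.6,0.1,1.4
carbon_mg_m2,raster_cells,2.0,6.4,1.8,0.6,1.2,15.0,2.7,0.7,3.8
carbon_mg_m2,aggregate_list,0.8,8.0,0.1,0.2,0.3,20.4,2.7,0.1,4.1
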