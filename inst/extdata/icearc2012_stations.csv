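station,latitude_deg,longitude_deg,coverage_pct,abundance_per_m2,diameter_median_cm,diameter_mean_cm,circularity,eccentricity,patchiness_index,slope,slope_gt2cm,slope_gt2cm_r2_low
ICE-1,84.00,30.00,0.026,2.8,2.1,2.5,0.79,0.79,11.5,-1.9,-3.0,FALSE
ICE-2,83.95,76.85,0.062,5.6,2.0,2.9,0.77,0.81,9.2,-2.2,-3.0,FALSE
ICE-3,82.86,109.86,0.005,0.4,3.4,4.1,0.66,0.89,67.4,-1.3,-0.6,TRUE
ICE-5,82.88,130.76,0.003,0.3,2.1,2.9,0.70,0.87,17.9,-1.7,-1.2,TRUE
ICE-6,85.06,122.52,0.008,1.1,1.6,2.2,0.68,0.85,74.0,-2.3,-2.0,TRUE
ICE-7,87.93,60.95,0.163,3.8,3.5,4.0,0.64,0.88,3.1,-2.2,-3.2,FALSE
ICE-8,88.83,58.53,0.093,16.0,2.0,2.4,0.71,0.87,3.3,-3.1,-3.9,FALSE
ICE-9,84.35,17.73,0.004,0.4,1.5,2.1,0.84,0.76,5.2,-1.6,-1.0,TRUE
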