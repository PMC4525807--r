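# Output column dictionary

## detections.csv (one row per detected region)
| column | unit | meaning |
|---|---|---|
| frame_id | - | frame the region was detected in |
| region_id | - | component id within the frame |
| area_m2 | m^2 | region area at the frame's metric scale |
| perimeter_m | m | boundary-step contour perimeter |
| ecd_cm | cm | equivalent circular diameter, 2 sqrt(A/pi) |
| major_cm, minor_cm | cm | fitted-ellipse full axes |
| eccentricity | - | sqrt(1 - (minor/major)^2); 0 circle, ->1 filament |
| circularity | - | 4 pi A / P^2; 1 for a perfect circle |
| orientation_rad | rad | ellipse orientation (image coordinates) |
| centroid_x_px, centroid_y_px | px | centroid in crop coordinates |
| pixel_area | px | raw component pixel count |
| solidity | - | area / convex-hull lattice area |
| measurable | - | TRUE when pixel_area > 10 (shape statistics) |
| clump_flag | - | TRUE when flagged as merged close-lying aggregates |

## frame_summaries.csv (one row per QC-passed frame)
| column | unit | meaning |
|---|---|---|
| t_s | s | capture time |
| depth_m | m | ROV depth |
| tilt_deg | deg | ROV tilt |
| altimeter_m | m | distance to the ice underside |
| x_m, y_m | m | floe-fixed frame-centre position |
| draft_m | m | ice draft, depth - altimeter (clipped at 0) |
| footprint_m2 | m^2 | metric area of the 250 x 200 px analysis crop |
| n_aggregates | - | all detections (incl. detect-only and clumps) |
| abundance | m^-2 | n_aggregates / footprint |
| coverage | fraction | summed aggregate area / footprint |
| mean_ecd_cm, median_ecd_cm | cm | over measurable, unflagged detections |
| mean_eccentricity, mean_circularity | - | same selection |

## grid_cells.csv (one row per occupied 3 x 3 m cell)
| column | unit | meaning |
|---|---|---|
| i, j | - | cell indices from the stored origin (half-open cells) |
| x_center_m, y_center_m | m | cell centre |
| n_frames | - | frames whose nadir lies in the cell |
| abundance, coverage, mean_draft_m, mean_eccentricity | as above | frame means |
| mean_ecd_cm, median_ecd_cm | cm | pooled over the cell's aggregates |
| n_aggregates, n_measurable | - | totals in the cell |
| roughness_m | m | sample sd of draft over the cell + 8 neighbours |

## biovolume.csv (one row per estimation method)
| column | unit | meaning |
|---|---|---|
| method | - | aggregate_list, global_mean, global_median, gridded_mean, gridded_median, raster_cells |
| V_ml_m2 | ml m^-2 | biovolume per unit ice area |
| a_per_m2 | m^-2 | abundance entering the estimate |
| d_cm | cm | diameter entering the estimate (if one exists) |
| carbon_mg_m2 | mg C m^-2 | V x 0.39 mg C ml^-1 |
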