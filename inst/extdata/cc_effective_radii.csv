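roi_id,hist_reff_um,t2_pred_um,t1_pred_um
ROI0,0.632,0.515,0.571
ROI1,0.777,0.533,0.511
ROI2,0.592,0.634,0.547
ROI3,0.638,0.723,0.616
ROI4,0.759,0.789,0.844
ROI5,0.855,1.069,1.047
ROI6,0.953,1.129,1.123
ROI7,0.633,0.750,0.791
ROI8,0.572,0.673,0.832
ROI9,0.583,0.836,0.782
ROI10,0.741,0.803,0.794
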