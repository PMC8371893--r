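claim_id,new_key,old_key,direction,use_abs,printed_percent,reproducible,note
db_vs_dr_linear_r2,lin_r2_Db,lin_r2_Dr,increase,FALSE,25.0,TRUE,
db_vs_dy_linear_r2,lin_r2_Db,lin_r2_Dy,increase,FALSE,11.1,TRUE,
sdb_vs_sdr_linear_r2,lin_r2_SDb,lin_r2_SDr,increase,FALSE,55.8,TRUE,
sdb_vs_sdy_linear_r2,lin_r2_SDb,lin_r2_SDy,increase,FALSE,11.0,TRUE,
nd705_d1_vs_orig_cor,cor_ND705_d1,cor_ND705_orig,increase,TRUE,18.4,TRUE,correlation magnitudes compared
ci_d1_vs_orig_cor,cor_CI_d1,cor_CI_orig,increase,TRUE,20.3,TRUE,correlation magnitudes compared
nd705_quad_r2_d1_vs_orig,quad_r2_ND705_d1,quad_r2_ND705_orig,increase,FALSE,53.4,FALSE,printed table values give 43.1; likely computed from unrounded metrics
ci_linear_rmse_d1_vs_orig,lin_rmse_CI_d1,lin_rmse_CI_orig,reduction,FALSE,45.6,TRUE,
wnn_modeling_r2_blue_vs_d1,wnn_mod_r2_blue,wnn_mod_r2_d1,increase,FALSE,8.6,TRUE,
wnn_modeling_rmse_blue_vs_d1,wnn_mod_rmse_blue,wnn_mod_rmse_d1,reduction,FALSE,18.7,TRUE,
wnn_modeling_mae_blue_vs_d1,wnn_mod_mae_blue,wnn_mod_mae_d1,reduction,FALSE,20.5,TRUE,
wnn_validation_r2_blue_vs_d1,wnn_val_r2_blue,wnn_val_r2_d1,increase,FALSE,7.3,TRUE,
wnn_validation_rmse_blue_vs_d1,wnn_val_rmse_blue,wnn_val_rmse_d1,reduction,FALSE,25.2,FALSE,printed table values give 25.3; likely computed from unrounded metrics
wnn_validation_mae_blue_vs_d1,wnn_val_mae_blue,wnn_val_mae_d1,reduction,FALSE,30.9,TRUE,
wnn_vs_rf_d1_rmse,wnn_val_rmse_d1,rf_val_rmse_d1,reduction,FALSE,5.4,TRUE,
wnn_vs_rf_d1_mae,wnn_val_mae_d1,rf_val_mae_d1,reduction,FALSE,10.5,TRUE,
wnn_vs_rbf_d1_rmse,wnn_val_rmse_d1,rbf_val_rmse_d1,reduction,FALSE,1.0,FALSE,printed table values give 1.1; likely computed from unrounded metrics
wnn_vs_rbf_d1_mae,wnn_val_mae_d1,rbf_val_mae_d1,reduction,FALSE,5.6,TRUE,
wnn_vs_bp_d1_rmse,bp_val_rmse_d1,wnn_val_rmse_d1,increase,FALSE,17.2,TRUE,source arithmetic expresses this as the BP excess over WNN
wnn_vs_bp_d1_mae,wnn_val_mae_d1,bp_val_mae_d1,reduction,FALSE,16.0,TRUE,
wnn_vs_rf_blue_r2,wnn_val_r2_blue,rf_val_r2_blue,increase,FALSE,7.3,TRUE,
wnn_vs_rf_blue_rmse,wnn_val_rmse_blue,rf_val_rmse_blue,reduction,FALSE,17.7,TRUE,
wnn_vs_rf_blue_mae,wnn_val_mae_blue,rf_val_mae_blue,reduction,FALSE,21.7,TRUE,
wnn_vs_rbf_blue_r2,wnn_val_r2_blue,rbf_val_r2_blue,increase,FALSE,8.6,TRUE,
wnn_vs_rbf_blue_rmse,wnn_val_rmse_blue,rbf_val_rmse_blue,reduction,FALSE,18.8,TRUE,
wnn_vs_rbf_blue_mae,wnn_val_mae_blue,rbf_val_mae_blue,reduction,FALSE,23.0,TRUE,
wnn_vs_bp_blue_r2,wnn_val_r2_blue,bp_val_r2_blue,increase,FALSE,14.3,TRUE,
wnn_vs_bp_blue_rmse,wnn_val_rmse_blue,bp_val_rmse_blue,reduction,FALSE,27.0,TRUE,
wnn_vs_bp_blue_mae,wnn_val_mae_blue,bp_val_mae_blue,reduction,FALSE,27.7,TRUE,
rf_blue_vs_d1_rmse,rf_val_rmse_blue,rf_val_rmse_d1,reduction,FALSE,14.1,TRUE,
rf_blue_vs_d1_mae,rf_val_mae_blue,rf_val_mae_d1,reduction,FALSE,21.1,TRUE,
rbf_blue_vs_d1_rmse,rbf_val_rmse_blue,rbf_val_rmse_d1,reduction,FALSE,9.1,TRUE,
rbf_blue_vs_d1_mae,rbf_val_mae_blue,rbf_val_mae_d1,reduction,FALSE,15.3,TRUE,
bp_blue_vs_d1_r2,bp_val_r2_blue,bp_val_r2_d1,increase,FALSE,4.1,TRUE,
bp_blue_vs_d1_rmse,bp_val_rmse_blue,bp_val_rmse_d1,reduction,FALSE,12.7,TRUE,
bp_blue_vs_d1_mae,bp_val_mae_blue,bp_val_mae_d1,reduction,FALSE,19.8,TRUE,
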