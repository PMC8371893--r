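key,value,description
lin_r2_Dr,0.64,linear fit R-squared for red edge amplitude Dr
lin_r2_SDr,0.52,linear fit R-squared for red edge area SDr
lin_r2_Dy,0.72,linear fit R-squared for yellow edge amplitude Dy
lin_r2_SDy,0.73,linear fit R-squared for yellow edge area SDy
lin_r2_Db,0.80,linear fit R-squared for blue edge amplitude Db
lin_r2_SDb,0.81,linear fit R-squared for blue edge area SDb
cor_ND705_d1,-0.90,correlation of first-derivative ND705 with petiole nitrate
cor_ND705_orig,-0.76,correlation of original-reflectance ND705 with petiole nitrate
cor_CI_d1,-0.89,correlation of first-derivative CI red edge with petiole nitrate
cor_CI_orig,-0.74,correlation of original-reflectance CI red edge with petiole nitrate
quad_r2_ND705_d1,0.83,quadratic fit R-squared for first-derivative ND705
quad_r2_ND705_orig,0.58,quadratic fit R-squared for original-reflectance ND705
lin_rmse_CI_d1,0.92,linear fit RMSE (g/L) for first-derivative CI red edge
lin_rmse_CI_orig,1.69,linear fit RMSE (g/L) for original-reflectance CI red edge
wnn_mod_r2_blue,0.88,WNN modeling R-squared on blue edge parameters
wnn_mod_rmse_blue,0.74,WNN modeling RMSE (g/L) on blue edge parameters
wnn_mod_mae_blue,0.58,WNN modeling MAE (g/L) on blue edge parameters
wnn_mod_r2_d1,0.81,WNN modeling R-squared on first-derivative indices
wnn_mod_rmse_d1,0.91,WNN modeling RMSE (g/L) on first-derivative indices
wnn_mod_mae_d1,0.73,WNN modeling MAE (g/L) on first-derivative indices
wnn_val_r2_blue,0.88,WNN validation R-squared on blue edge parameters
wnn_val_rmse_blue,0.65,WNN validation RMSE (g/L) on blue edge parameters
wnn_val_mae_blue,0.47,WNN validation MAE (g/L) on blue edge parameters
wnn_val_r2_d1,0.82,WNN validation R-squared on first-derivative indices
wnn_val_rmse_d1,0.87,WNN validation RMSE (g/L) on first-derivative indices
wnn_val_mae_d1,0.68,WNN validation MAE (g/L) on first-derivative indices
rf_val_r2_blue,0.82,RF validation R-squared on blue edge parameters
rf_val_rmse_blue,0.79,RF validation RMSE (g/L) on blue edge parameters
rf_val_mae_blue,0.60,RF validation MAE (g/L) on blue edge parameters
rf_val_r2_d1,0.82,RF validation R-squared on first-derivative indices
rf_val_rmse_d1,0.92,RF validation RMSE (g/L) on first-derivative indices
rf_val_mae_d1,0.76,RF validation MAE (g/L) on first-derivative indices
rbf_val_r2_blue,0.81,RBF validation R-squared on blue edge parameters
rbf_val_rmse_blue,0.80,RBF validation RMSE (g/L) on blue edge parameters
rbf_val_mae_blue,0.61,RBF validation MAE (g/L) on blue edge parameters
rbf_val_r2_d1,0.82,RBF validation R-squared on first-derivative indices
rbf_val_rmse_d1,0.88,RBF validation RMSE (g/L) on first-derivative indices
rbf_val_mae_d1,0.72,RBF validation MAE (g/L) on first-derivative indices
bp_val_r2_blue,0.77,BP validation R-squared on blue edge parameters
bp_val_rmse_blue,0.89,BP validation RMSE (g/L) on blue edge parameters
bp_val_mae_blue,0.65,BP validation MAE (g/L) on blue edge parameters
bp_val_r2_d1,0.74,BP validation R-squared on first-derivative indices
bp_val_rmse_d1,1.02,BP validation RMSE (g/L) on first-derivative indices
bp_val_mae_d1,0.81,BP validation MAE (g/L) on first-derivative indices
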