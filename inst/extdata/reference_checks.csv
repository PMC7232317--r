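id,quantity,printed,tolerance,cmp,provenance
coef_intercept,Intercept of the coded quadratic equation,94.23,0.4712,eq,reported regression equation
coef_pH,Linear pH coefficient (A),-0.1231,0.005,eq,reported regression equation
coef_temperature,Linear temperature coefficient (B),-0.2929,0.005,eq,reported regression equation
coef_time,Linear incubation-time coefficient (C),4.04,0.0202,eq,reported regression equation
coef_pH_temperature,pH x temperature interaction (AB),-1.25,0.00625,eq,reported regression equation
coef_pH_time,pH x time interaction (AC) magnitude,2.00,0.02,mag,reported regression equation (sign discrepancy: refit gives -2.00)
coef_temperature_time,temperature x time interaction (BC),-4.50,0.0225,eq,reported regression equation
coef_pH2,Quadratic pH coefficient (A^2),-6.74,0.0337,eq,reported regression equation
coef_temperature2,Quadratic temperature coefficient (B^2),-6.91,0.03455,eq,reported regression equation
coef_time2,Quadratic time coefficient (C^2),-5.11,0.02555,eq,reported regression equation
adj_r_squared,Adjusted R-squared of the quadratic fit,0.9823,0.002,eq,reported ANOVA summary (labelled simply R-squared there)
pred_r_squared,Prediction R-squared (PRESS-based),0.9412,0.01,eq,reported ANOVA summary
cv_percent,Coefficient of variation (%),1.64,0.05,eq,reported ANOVA summary
f_value,Regression F statistic,143.23,2.8646,eq,reported ANOVA summary
boxcox_lambda,Best Box-Cox lambda,1.72,0.15,eq,reported transformation scan
boxcox_lo,Box-Cox interval lower bound,-0.45,0.5,eq,reported transformation scan (matches a 99% profile cutoff)
boxcox_hi,Box-Cox interval upper bound,4.24,0.5,eq,reported transformation scan (matches a 99% profile cutoff)
stationary_predicted,Predicted response quoted at the stationary point,95.6,NA,note,reported optimum; inconsistent with the quoted equation at its own optimum (94.23)
control_half_life,Control half-life from k = 0.0013 1/h,533.19,0.005,eq,reported kinetics results
treatment_half_life,Treatment half-life quoted for k = 0.0193 1/h,26.05,NA,note,reported kinetics results; ln(2)/0.0193 = 35.91 h - quoted pair is internally inconsistent
half_life_reduction,Half-life reduction vs control (h),507.1,0.1,eq,reported kinetics comparison (difference of the quoted half-lives)
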