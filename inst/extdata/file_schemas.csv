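file,column,type,description
stations.csv,station_id,string,unique monitor id
stations.csv,region,string,region name
stations.csv,lon,double,longitude decimal degrees
stations.csv,lat,double,latitude decimal degrees
stations.csv,pollutant,string,"one of NO2, O3, PM2.5, PM10"
stations.csv,week,integer,calendar week index from study_start
stations.csv,value,double,weekly concentration (ppb gases / ug/m3 PM); empty = missing
residences.csv,subject_id,string,subject id
residences.csv,start_date,date,ISO-8601 interval start (inclusive)
residences.csv,end_date,date,ISO-8601 interval end (exclusive)
residences.csv,lon,double,longitude decimal degrees
residences.csv,lat,double,latitude decimal degrees
cohort.csv,subject_id,string,subject id
cohort.csv,region,string,recruitment region (East/West)
cohort.csv,gestational_age,double,gestational age at birth in weeks
cohort.csv,conception_date,date,conception date
cohort.csv,birth_date,date,birth date
cohort.csv,sex,string,child sex
cohort.csv,race_ethnicity,string,maternal race/ethnicity
cohort.csv,education,string,maternal education
cohort.csv,birth_year_band,string,year-of-birth band
betas.csv,cpg_id,string,first column; remaining columns are samples
exposures.csv,subject_id,string,subject id
exposures.csv,pollutant,string,pollutant
exposures.csv,week,integer,grid week 1..52 (1-13 preconception; 14-52 pregnancy)
exposures.csv,value,double,interpolated weekly concentration
exposures.csv,flag,string,observed | padded | missing
periods.csv,pollutant,string,pollutant
periods.csv,subject_id,string,subject id
periods.csv,preconception,double,period mean concentration
periods.csv,trimester1,double,period mean concentration
periods.csv,trimester2,double,period mean concentration
periods.csv,trimester3,double,period mean concentration
periods.csv,pregnancy,double,period mean concentration
period_results.csv,clock,string,clock name
period_results.csv,pollutant,string,pollutant
period_results.csv,period,string,exposure period
period_results.csv,model_type,string,individual | mutually_adjusted
period_results.csv,beta,double,weeks acceleration per scale_per units
period_results.csv,se,double,classical standard error (same scale)
period_results.csv,ci_low,double,t-based 95% CI lower bound
period_results.csv,ci_high,double,t-based 95% CI upper bound
period_results.csv,p_value,double,two-sided p-value
period_results.csv,n_used,integer,complete cases used
lag_curves.csv,clock,string,clock name
lag_curves.csv,pollutant,string,pollutant
lag_curves.csv,week,integer,grid week 1..52
lag_curves.csv,beta,double,weeks acceleration per scale_per units at that week
lag_curves.csv,se,double,delta-method standard error
lag_curves.csv,ci_low,double,pointwise 95% CI lower bound
lag_curves.csv,ci_high,double,pointwise 95% CI upper bound
lag_curves.csv,significant,logical,CI excludes zero
clock coefficient CSV,cpg_id,string,CpG id; reserved id (Intercept) holds the intercept
clock coefficient CSV,coefficient,double,linear-predictor weight in the clock's output units
cell reference CSV,cpg_id,string,first column; remaining 7 columns are cell types
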