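species_id,genus,n_measured,rel_head,aspect_ratio,rel_eye,eye_position,mouth_angle,rel_sam,rel_gape,guild,lmax_cm
Alepocephalus agassizii,Alepocephalus,22,0.29,3.11,0.074,Side,25.6,0.34,75.7,pelagic,123.0
Alepocephalus bairdii,Alepocephalus,19,0.21,5.29,0.065,Side,23.3,0.19,43.8,pelagic,127.4
Antimora rostrata,Antimora,16,0.21,2.77,0.044,Side,16.5,0.17,58.2,unknown,87.0
Aphanopus carbo,Aphanopus,19,0.19,3.09,0.032,Side,16.9,0.00,55.8,pelagic_high,129.0
Apristurus aphyodes,Apristurus,13,0.24,0.38,0.013,Side,9.3,0.00,20.4,benthic,85.0
Argentina silus,Argentina,20,0.19,3.53,0.087,Side,26.5,0.13,14.9,pelagic,81.1
Bathypterois dubius,Bathypterois,18,0.16,3.10,0.010,Side,21.1,0.17,24.8,unknown,29.0
Bathysaurus ferox,Bathysaurus,6,0.14,2.19,0.018,Side,28.8,0.00,97.2,unknown,74.2
Beryx decadactylus,Beryx,17,0.24,3.93,0.111,Side,35.1,1.30,93.4,unknown,100.0
Cataetyx laticeps,Cataetyx,10,0.21,NA,0.020,Top,28.2,0.51,101.1,benthic_suspension,101.0
Centroscymnus coelolepis,Centroscymnus,1,0.15,2.58,0.021,Side,NA,NA,35.5,benthic,122.0
Chimaera monstrosa,Chimaera,19,0.15,NA,0.037,Side,48.3,0.08,7.9,benthic,150.0
Coelorinchus caelorhincus,Coelorinchus,16,0.18,NA,0.045,Side,50.9,0.10,10.2,benthic_low,48.0
Coelorinchus labiatus,Coelorinchus,20,0.26,NA,0.046,Side,57.7,0.12,5.9,unknown,50.0
Coryphaenoides guentheri,Coryphaenoides,21,0.17,NA,0.044,Side,35.6,0.06,6.7,benthic,55.3
Coryphaenoides mediterraneus,Coryphaenoides,19,0.10,NA,0.023,Side,47.5,0.19,19.8,benthic_low,105.8
Coryphaenoides rupestris,Coryphaenoides,29,0.15,NA,0.038,Side,56.0,0.27,25.4,pelagic,127.7
Halargyreus johnsonii,Halargyreus,20,0.22,2.72,0.061,Side,42.7,0.22,27.9,unknown,56.0
Halosauropsis macrochir,Halosauropsis,11,0.13,NA,0.012,Side,44.7,0.08,15.9,benthic_high,90.0
Harriotta raleighana,Harriotta,9,0.30,NA,0.027,Side,NA,NA,6.6,unknown,120.0
Helicolenus dactylopterus,Helicolenus,20,0.31,2.27,0.076,Side,46.5,0.67,76.3,benthic,47.0
Hoplostethus atlanticus,Hoplostethus,15,0.30,3.82,0.067,Side,40.2,0.82,140.8,benthic,75.0
Hydrolagus affinis,Hydrolagus,9,0.20,0.49,0.029,Side,NA,NA,19.3,unknown,131.6
Lepidion eques,Lepidion,20,0.20,0.92,0.061,Middle,42.9,0.16,27.0,benthic_low,44.0
Merluccius merluccius,Merluccius,6,0.20,1.41,0.036,Middle,26.7,0.50,85.0,benthic_high,140.0
Mora moro,Mora,20,0.18,1.89,0.064,Middle,32.6,0.37,66.8,unknown,80.0
Nezumia aequalis,Nezumia,17,0.16,NA,0.057,Middle,31.0,0.06,7.6,benthic_high,37.8
Phycis blennoides,Phycis,20,0.19,1.33,0.048,Mixed,33.6,0.55,49.8,benthic,110.0
Spectrunculus grandis,Spectrunculus,14,0.16,NA,0.024,Mixed,32.9,0.24,30.5,unknown,147.3
Synaphobranchus kaupii,Synaphobranchus,20,0.11,NA,0.013,Side,50.4,0.00,9.6,benthic_low,100.0
Trachyrincus murrayi,Trachyrincus,20,0.20,NA,0.036,Side,54.1,0.15,17.7,benthic_low,66.7
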