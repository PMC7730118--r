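measurand,material,x_pt,u_xpt,R,r,rsd_R_pct,rsd_r_pct
mean_diameter,candies,158,9.1,12.3,3.1,7.8,2.0
mean_diameter,chewing_gum,149,10.3,14.4,5.8,9.7,3.9
mean_diameter,pristine_e171,163,15.5,19.2,3.6,11.8,2.2
mode_diameter,candies,104,3.5,7.1,6.5,6.8,6.3
mode_diameter,chewing_gum,97,5.2,10.0,8.8,10.3,9.1
mode_diameter,pristine_e171,95,8.6,11.4,5.2,12.0,5.5
pct_below_100,candies,26.0,3.4,4.6,1.0,17.6,3.7
pct_below_100,chewing_gum,30.2,4.0,5.6,2.4,18.7,7.8
pct_below_100,pristine_e171,27.7,3.9,5.0,2.0,18.1,7.2
d10,candies,71,4.0,5.7,2.5,7.9,3.5
d10,chewing_gum,66,4.7,6.8,3.3,10.2,5.1
d10,pristine_e171,69,2.9,4.7,3.8,6.9,5.5
d50,candies,146,7.8,10.7,3.3,7.3,2.3
d50,chewing_gum,136,8.7,12.6,6.3,9.3,4.6
d50,pristine_e171,149,10.1,12.7,3.7,8.6,2.5
d99_5,candies,415,52.5,71.1,18.5,17.1,4.5
d99_5,chewing_gum,405,43.2,59.3,18.9,14.6,4.7
d99_5,pristine_e171,428,81.5,100.6,15.6,23.5,3.6
d99_8,candies,455,72.7,97.5,19.7,21.4,4.3
d99_8,chewing_gum,457,78.4,106.5,29.3,23.3,6.4
d99_8,pristine_e171,475,103.6,127.8,18.4,26.9,3.9
d0,candies,38,13.4,17.8,1.7,46.5,4.6
d0,chewing_gum,38,13.6,18.0,1.6,47.0,4.2
d0,pristine_e171,38,16.1,19.8,1.9,52.5,4.9
d100,candies,482,150.5,202.9,48.0,42.1,10.0
d100,chewing_gum,461,134.4,183.0,53.6,39.7,11.6
d100,pristine_e171,561,161.6,206.8,73.5,36.9,13.1
total_particles_in_sample,candies,4.1E11,9.7E10,1.3E11,3.8E10,32.2,9.2
total_particles_in_sample,chewing_gum,3.5E11,9.1E10,1.3E11,4.6E10,35.9,13.1
total_particles_in_sample,pristine_e171,1.1E12,3.8E11,4.7E11,1.3E11,43.1,11.4
particles_per_g,candies,7.4E10,1.7E10,2.3E10,7.7E09,31.4,10.3
particles_per_g,chewing_gum,8.3E10,2.2E10,3.0E10,1.1E10,36.5,12.7
particles_per_g,pristine_e171,2.7E13,9.3E12,1.2E13,3.3E12,43.5,12.4
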