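# CSDA range versus kinetic energy in liquid water (unit density), used by
# the straight-track transport engine. Values compiled by the package
# authors from standard published CSDA range tabulations for electrons and
# alpha particles in liquid water (NIST ESTAR/ASTAR-style reference data),
# rounded to ~1-3% precision; ranges in g/cm^2 equal cm at 1 g/cm^3.
# Log-log interpolation between rows; power-law extrapolation below the
# first row.
particle,energy_keV,csda_range_cm
electron,1,5.0e-06
electron,2,1.6e-05
electron,3,3.1e-05
electron,5,7.7e-05
electron,7,1.4e-04
electron,10,2.515e-04
electron,20,8.57e-04
electron,30,1.76e-03
electron,40,2.92e-03
electron,50,4.32e-03
electron,70,7.73e-03
electron,100,1.431e-02
electron,150,2.79e-02
electron,200,4.49e-02
electron,300,8.42e-02
electron,400,1.29e-01
electron,500,1.766e-01
electron,700,2.74e-01
electron,1000,4.367e-01
electron,1500,7.00e-01
electron,2000,9.785e-01
electron,3000,1.514e+00
electron,4000,2.037e+00
alpha,250,2.0e-04
alpha,500,3.0e-04
alpha,1000,5.5e-04
alpha,2000,1.05e-03
alpha,3000,1.65e-03
alpha,4000,2.40e-03
alpha,5000,3.55e-03
alpha,6000,4.80e-03
alpha,7000,6.00e-03
alpha,8000,7.35e-03
alpha,9000,8.80e-03
alpha,10000,1.03e-02
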