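# Emission data for the five supported therapeutic radionuclides.
# Electron (beta + conversion-electron + Auger) emissions are stored as
# energy-binned totals (bin_lo_keV, bin_hi_keV, energy_per_decay_keV);
# a representative line energy and yield are derived at load time.
# Alpha and photon emissions are stored as discrete lines
# (energy_keV, yield_per_decay). Photons are excluded from all dose
# computations. The 225Ac rows describe the full decay chain to stable
# 209Bi, assumed to decay in situ.
nuclide,particle_class,bin_lo_keV,bin_hi_keV,energy_per_decay_keV,energy_keV,yield_per_decay
90Y,electron,0.01,10,0,,
90Y,electron,10,50,1,,
90Y,electron,50,100,2,,
90Y,electron,100,200,7,,
90Y,electron,200,1000,294,,
90Y,electron,1000,9000,630,,
131I,electron,0.01,10,1,,
131I,electron,10,50,6,,
131I,electron,50,100,13,,
131I,electron,100,200,41,,
131I,electron,200,1000,129,,
131I,electron,1000,9000,0,,
177Lu,electron,0.01,10,2,,
177Lu,electron,10,50,9,,
177Lu,electron,50,100,16,,
177Lu,electron,100,200,52,,
177Lu,electron,200,1000,67,,
177Lu,electron,1000,9000,0,,
161Tb,electron,0.01,10,9,,
161Tb,electron,10,50,43,,
161Tb,electron,50,100,16,,
161Tb,electron,100,200,45,,
161Tb,electron,200,1000,87,,
161Tb,electron,1000,9000,0,,
225Ac,electron,0.01,10,6,,
225Ac,electron,10,50,18,,
225Ac,electron,50,100,24,,
225Ac,electron,100,200,62,,
225Ac,electron,200,1000,504,,
225Ac,electron,1000,9000,52,,
225Ac,alpha,,,,5787,1
225Ac,alpha,,,,6304,1
225Ac,alpha,,,,7068,1
225Ac,alpha,,,,5846,0.021
225Ac,alpha,,,,8377,0.979
131I,photon,,,,364,0.82
131I,photon,,,,637,0.07
177Lu,photon,,,,113,0.06
177Lu,photon,,,,208,0.11
161Tb,photon,,,,26,0.23
161Tb,photon,,,,49,0.17
161Tb,photon,,,,75,0.10
225Ac,photon,,,,218,0.11
225Ac,photon,,,,440,0.26
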