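# Physical half-lives and the maximum beta endpoint energy of the decay
# (for 225Ac: of the dominant beta branch in the chain, 213Bi). Endpoints
# cap the representative energies of the binned electron spectra.
nuclide,half_life_days,beta_endpoint_keV
90Y,2.7,2280
131I,8.0,606
177Lu,6.6,498
161Tb,6.9,593
225Ac,10.2,1423
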