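# rasta-photons v1
# wavelength 2.5
# i0_eff 1e-06
# kmax 3
# n_images 3
# provenance {"generator":"handcrafted-conformance-vector","seed":0}
# columns image_id k_x k_y
0 0.5 -0.25
0 -1 1.25
1 . .
2 2 0.125
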