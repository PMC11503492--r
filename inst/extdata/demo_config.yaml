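# Toy 3 x 4 demo screen: small droplet count, three planted actives.
bb_table: demo_bb.csv            # resolved relative to the working dir
out_dir: demo_out
n_droplets: 20000
droplet_rate: 400
bead_lambda: 0.06
control_bead_fraction: 0.02
active_map:
  S1-A2: 0.9
  S2-A4: 1.0
sample_size: 200
n_samples: 3
seed: 7
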