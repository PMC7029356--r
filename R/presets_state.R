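# Stored resting initial conditions for the shipped presets: the state
# reached after 200 conditioning beats of 1 Hz pacing of the default
# models (regenerate with steady_state(model_parameters(preset), 200)).

.adult_rest <- c(
  -84.02090182, 0.002215840943, 0.7101523124, 0.7102024707, 0.0004009755174, 0.3792383596, 2.655895982e-05, 0.9983712188, 0.9996689177, 2.9560301e-08, 0.9999972509, 0.0002513537546, 0.9861847236, 0.003524979713, 0.2749191727, 2.756461571e-05, 0.0004082279681, 1.401214138e-05, 0.2008387496, 0.2049446276, 0.002118495864, 0.01217754638, 0.00161484865, 1.416202196, 0.6651474969
)

.hipsc_rest <- c(
  -80.11311265, 0.005006691259, 0.581257263, 0.6078304137, 0.0008420122624, 0.3050024077, 4.470301688e-05, 0.9971609108, 0.9994710773, 5.642357773e-08, 0.9999940662, 0.0004102612818, 0.9821756566, 0.004653806222, 0.249288254, 3.49306288e-05, 4.844667608e-05, 8.205297151e-06, 0.1453873231, 0.1489243645, 0.009509272592, 0.003710100452, 0.002238936374, 2.61115681, 0.710898864
)

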