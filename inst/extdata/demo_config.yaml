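# Small demonstration configuration for `tiletrack track` /
# `tiletrack simulate` and run_pipeline(). Runs in well under a minute.
seed: 7
output_dir: tiletrack_demo_output
geometry:
  gantry_deg: 30
  imager_deg: 45
  detector_px: 128
  pitch_mm: 3.2
  step_mm: 2
motion:
  pattern: sinusoid
  amplitude_mm: [3, 2, 20]
  period_s: 4
  frame_rate_hz: 5
  n_frames: 10
distortion:
  gamma: 1.3
  bias_amplitude: 0.1
  noise_sd: 0.02
localization:
  subpixel: true
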