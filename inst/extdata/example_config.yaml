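# Example run configuration. Every value shown equals the package default;
# uncomment and edit to override.
motion:
  diff_threshold: 50     # grayscale units; pixels changing by more count as moving
  eps_low: 0.5           # coverage band (percent of frame) scoring 100
  eps_high: 20
  interval: 0.3          # seconds between the frames of a pair
exposure:
  saturation_threshold: 245
  min_blob_area: 0.02    # percent of frame; smaller blobs are noise
  opening_size: 3        # square opening kernel; 0 disables
efficiency:
  t_max: 5               # minutes allowed for the procedure
  clamp_negative: true
stats:
  alpha: 0.05
  p_threshold: 0.01
  test: welch            # welch | pooled | wilcoxon
  normality: ks          # ks | lilliefors
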