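# Shared fixtures: templates are deterministic, build once per session.
tpl <- build_default_templates()

# Sensitivity of R detection on a generated record against its own
# annotations, at the given matching tolerance.
se_on_record <- function(rec, tol_s = 0.075) {
  beats <- detect_beats(rec$signal, rec$fs)
  m <- match_events(sort(beats$r_time), sort(rec$annotations$r_time), tol_s)
  m$tp / (m$tp + m$fn)
}
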