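Package: ecgwave
Title: Wavelet Subband ECG Feature Detection and Myocardial Action-Potential Inverse Fitting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-lead electrocardiogram analysis built on discrete wavelet
    decomposition with principled subband scheduling: the decomposition level
    and branch isolating a physiological frequency band are chosen from the
    band's normalized center frequency, QRS complexes and T waves are located
    by an adaptive windowed-energy threshold on the extracted coefficients,
    and per-beat eigenvalues (R and T peak times and amplitudes, beat energy
    integral) drive an inverse fit of left/right epicardial action-potential
    scaling parameters (k, h_R, h_L) used to flag myocardial ischemia and
    heart failure. Includes an annotated synthetic ECG generator, detection
    scoring (sensitivity, detection error rate, accuracy), readers and
    writers for signal CSV and WFDB format-212 records, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
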