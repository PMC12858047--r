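Package: ecgtune
Title: End-to-End 12-Lead ECG Classification: Ingestion, Training and
    Fine-Tuning of Time-Series Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless toolkit for 12-lead resting electrocardiogram (ECG)
    classification. Reads ECG waveforms from CSV, NumPy, DICOM waveform,
    MATLAB, WFDB-style DAT and XML containers into a uniform record type;
    normalizes them by Fourier resampling to a configurable rate (default
    100 Hz), 12-lead / 10-second standardization and millivolt scaling at a
    1000 ADU/mV gain; detects R peaks and computes median beats; provides
    native InceptionTime and XceptionTime convolutional classifiers with
    parameter and FLOP accounting; imports and exports models in the ONNX
    interchange format (Opset <= 20) with automatic classification-head
    adaptation and layer freezing; runs a fixed one-command training
    protocol (AdamW, learning-rate finder, exponential decay, stratified
    80/20 split, weighted-validation-loss checkpointing, early stopping);
    and evaluates predictions with confusion matrices, F1 families, Fmax
    threshold suggestion, ROC, calibration scores and bootstrap confidence
    intervals. A built-in synthetic ECG generator with known ground truth
    makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    signal,
    xml2,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    nnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
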