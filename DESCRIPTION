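Package: popfrisk
Title: Preoperative Risk Stratification for Postoperative Pancreatic Fistula
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Preoperative prediction of clinically relevant postoperative
    pancreatic fistula (CR-POPF) after pancreaticoduodenectomy. Implements a
    discrete Bayes classifier over cut-off-discretized clinical markers,
    leave-one-out wrapper selection of the optimal marker combination, a
    diagnosis-stratified final prediction model (main pancreatic duct index
    for pancreatic ductal adenocarcinoma; duct index plus body mass index
    otherwise), confusion-matrix performance metrics, and a calibrated
    synthetic-cohort generator so the whole workflow is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
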