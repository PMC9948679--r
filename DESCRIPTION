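Package: reflexop
Title: Closed-Loop Operant Conditioning of Stimulus-Evoked Muscle Responses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computational engine for evoked-potential operant-conditioning
    protocols such as soleus H-reflex down-conditioning. Converts streaming
    surface EMG into background-activity traces, decides frame by frame when a
    contingent electrical stimulus may be delivered, extracts stimulus-locked
    epochs and quantifies M-wave (reference) and H-reflex (target) response
    sizes, aggregates trials into recruitment curves and response-size
    distributions, derives percentile-based conditioning criteria, and manages
    sessions, runs and logs. A built-in virtual participant generates
    physiologically structured synthetic EMG with sigmoidal M-wave and
    rise-then-fall H-reflex recruitment and optional reinforcement-driven
    plasticity, so the whole closed loop can be exercised without hardware.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
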