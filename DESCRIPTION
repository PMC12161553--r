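Package: dhnnforecast
Title: Discrete Hopfield Networks with Markov-Derived Thresholds for
    Athlete Training-Performance Forecasting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forecasts football athletes' training performance from seven
    ordinal training indicators (strength, speed, endurance, regional,
    resisted-stress, recovery and basic-skill training) with a discrete
    Hopfield neural network whose per-neuron activation thresholds are
    extracted from an m-step Markov probability transition matrix built
    from the training score matrix. Includes the rule-based indicator
    scoring scheme, Hebbian prototype storage with asynchronous
    sign-threshold dynamics and energy-descent convergence, a
    train/test/validation evaluation pipeline (accuracy, precision,
    recall, F1, G-score), a synthetic session-table generator emulating a
    20-athlete by 30-day by 4-session study design, and indicator
    importance analysis via Pearson correlation and k-means clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
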