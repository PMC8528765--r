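# Versioned instrument catalog: item counts, reversal keys, aggregation and
# cut-offs for the monitoring battery.
#
# Item ranges: HSCL-11 items 0-3; ASC, ASQ and OQ-30 items 1-5.
# Directions are inclusive as printed (<= / >=).
#
# The ASC block layout (TA 1-11, MO 12-20, SS 21-31, LE 32-40) and the
# reversal keys are SYNTHETIC: the published form's item order and reversal
# key are proprietary and are not reproduced here. They are configuration,
# not ground truth; swap in the licensed key for use with real ASC data.
#
# ASQ domain cut-offs are not stored: they are derived at load time as
# mean - 1 SD from the archival session-5 moments below (N = 1150 outpatient
# archive). HSCL_total has no domain cut-off (it is the tracked outcome, not
# a CST domain); OQ-30 enters only through risk items 5 and 18.
version: 1
scales:
  HSCL_total:
    instrument: HSCL11
    items: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11]
    reversed: []
    aggregation: mean
    range: [0, 3]
    domain_cutoff: ~
    cutoff_direction: ~
    item_cutoff: ~
  ASC_TA:
    instrument: ASC
    items: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11]
    reversed: [3, 7]
    aggregation: sum
    range: [1, 5]
    domain_cutoff: 39
    cutoff_direction: at_or_below
    item_cutoff: 2
  ASC_MO:
    instrument: ASC
    items: [12, 13, 14, 15, 16, 17, 18, 19, 20]
    reversed: [14, 18]
    aggregation: sum
    range: [1, 5]
    domain_cutoff: 32
    cutoff_direction: at_or_below
    item_cutoff: 2
  ASC_SS:
    instrument: ASC
    items: [21, 22, 23, 24, 25, 26, 27, 28, 29, 30, 31]
    reversed: [23, 29]
    aggregation: sum
    range: [1, 5]
    domain_cutoff: 23
    cutoff_direction: at_or_below
    item_cutoff: 2
  ASC_LE:
    instrument: ASC
    items: [32, 33, 34, 35, 36, 37, 38, 39, 40]
    reversed: [33, 36]
    aggregation: sum
    range: [1, 5]
    domain_cutoff: 23
    cutoff_direction: at_or_below
    item_cutoff: 2
  ASQ_concealing:
    instrument: ASQ
    items: [1, 2, 3, 4, 5, 6, 7, 8]
    reversed: [1, 2, 3, 4, 5, 6, 7, 8]
    aggregation: mean
    range: [1, 5]
    archival_mean: 3.01
    archival_sd: 0.74
    cutoff_direction: at_or_below
    item_cutoff: 2
  ASQ_tolerating:
    instrument: ASQ
    items: [9, 10, 11, 12, 13]
    reversed: []
    aggregation: mean
    range: [1, 5]
    archival_mean: 2.97
    archival_sd: 0.68
    cutoff_direction: at_or_below
    item_cutoff: 2
  ASQ_adjusting:
    instrument: ASQ
    items: [14, 15, 16, 17, 18, 19, 20]
    reversed: []
    aggregation: mean
    range: [1, 5]
    archival_mean: 2.45
    archival_sd: 0.75
    cutoff_direction: at_or_below
    item_cutoff: 2
  OQ_total:
    instrument: OQ30
    items: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16, 17, 18, 19,
            20, 21, 22, 23, 24, 25, 26, 27, 28, 29, 30]
    reversed: []
    aggregation: sum
    range: [1, 5]
    domain_cutoff: ~
    cutoff_direction: ~
    item_cutoff: ~
risk:
  # suicidality / substance-risk indicator items and their inclusive cut-offs
  hscl_suicide_item: 11
  hscl_cutoff: 2
  oq_items: [5, 18]
  oq_cutoff: 3
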