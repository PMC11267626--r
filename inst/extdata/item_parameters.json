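{
  "comment": "Calibrated synthetic GPCM item banks for a short (5-item) and a long (11-item) 3-category ADHD screening scale. Calibrated once by large-sample simulation so that, at n = 1551: Guttman lambda-2 is about 0.80 (source) and 0.82 (target), both sum-score distributions are right-skewed, and with trait_correlation 0.57 the between-scale sum-score Pearson correlation is about 0.43.",
  "n_categories": 3,
  "trait_correlation": 0.57,
  "source": [
    {"item_id": "src_1", "a": 1.85, "b": [0.4, 1.5]},
    {"item_id": "src_2", "a": 1.67, "b": [0.7, 1.9]},
    {"item_id": "src_3", "a": 2.02, "b": [0.5, 1.6]},
    {"item_id": "src_4", "a": 1.58, "b": [0.9, 2.1]},
    {"item_id": "src_5", "a": 1.76, "b": [0.6, 1.8]}
  ],
  "target": [
    {"item_id": "tgt_1",  "a": 1.22, "b": [0.5, 1.7]},
    {"item_id": "tgt_2",  "a": 1.04, "b": [0.8, 2.0]},
    {"item_id": "tgt_3",  "a": 1.30, "b": [0.4, 1.6]},
    {"item_id": "tgt_4",  "a": 0.96, "b": [1.0, 2.2]},
    {"item_id": "tgt_5",  "a": 1.13, "b": [0.6, 1.8]},
    {"item_id": "tgt_6",  "a": 1.39, "b": [0.3, 1.5]},
    {"item_id": "tgt_7",  "a": 0.87, "b": [1.1, 2.3]},
    {"item_id": "tgt_8",  "a": 1.17, "b": [0.7, 1.9]},
    {"item_id": "tgt_9",  "a": 1.09, "b": [0.9, 2.1]},
    {"item_id": "tgt_10", "a": 1.26, "b": [0.5, 1.8]},
    {"item_id": "tgt_11", "a": 1.00, "b": [1.2, 2.4]}
  ]
}
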