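# Published reference layer table for the modified U-Net segmenter
# (192x256x3 input). One entry per parameterized layer (convolutions and
# batch normalization), in network order, with the published per-row
# parameter cell. The published footer totals are kept verbatim; note the
# footer grand total exceeds the sum of the printed rows (see the package
# methods vignette) -- row cells and the non-trainable total are the
# quantities treated as ground truth.
layers:
  - {label: Conv_1, kind: conv, parameters: 1792}
  - {label: Batch Normalization 1, kind: batch_norm, parameters: 256}
  - {label: Conv 2, kind: conv, parameters: 36928}
  - {label: Batch Normalization 2, kind: batch_norm, parameters: 256}
  - {label: Conv_3, kind: conv, parameters: 73856}
  - {label: Batch Normalization 3, kind: batch_norm, parameters: 512}
  - {label: Conv 4, kind: conv, parameters: 147584}
  - {label: Batch Normalization 4, kind: batch_norm, parameters: 512}
  - {label: Conv 5, kind: conv, parameters: 295168}
  - {label: Batch Normalization 5, kind: batch_norm, parameters: 1024}
  - {label: Conv 6, kind: conv, parameters: 590080}
  - {label: Batch Normalization 6, kind: batch_norm, parameters: 1024}
  - {label: Conv 7, kind: conv, parameters: 590080}
  - {label: Batch Normalization 7, kind: batch_norm, parameters: 1024}
  - {label: Conv 8, kind: conv, parameters: 1180160}
  - {label: Batch Normalization 8, kind: batch_norm, parameters: 2048}
  - {label: Conv 9, kind: conv, parameters: 2359808}
  - {label: Batch Normalization 9, kind: batch_norm, parameters: 2048}
  - {label: Conv 10, kind: conv, parameters: 2359808}
  - {label: Batch Normalization 10, kind: batch_norm, parameters: 2048}
  - {label: Conv 11, kind: conv, parameters: 2359808}
  - {label: Batch Normalization 11, kind: batch_norm, parameters: 2048}
  - {label: Conv 12, kind: conv, parameters: 2359808}
  - {label: Batch Normalization 12, kind: batch_norm, parameters: 2048}
  - {label: Conv 13, kind: conv, parameters: 2359808}
  - {label: Batch Normalization 13, kind: batch_norm, parameters: 2048}
  - {label: De-Conv 1, kind: conv, parameters: 4719104}
  - {label: Batch Normalization 14, kind: batch_norm, parameters: 2048}
  - {label: De-Conv 2, kind: conv, parameters: 2359808}
  - {label: Batch Normalization 15, kind: batch_norm, parameters: 2048}
  - {label: De-Conv 3, kind: conv, parameters: 2359808}
  - {label: Batch Normalization 16, kind: batch_norm, parameters: 2048}
  - {label: De-Conv 4, kind: conv, parameters: 2359808}
  - {label: Batch Normalization 17, kind: batch_norm, parameters: 2048}
  - {label: De-Conv 5, kind: conv, parameters: 2359808}
  - {label: Batch Normalization 18, kind: batch_norm, parameters: 2048}
  - {label: De-Conv 6, kind: conv, parameters: 1179904}
  - {label: Batch Normalization 19, kind: batch_norm, parameters: 1024}
  - {label: De-Conv 7, kind: conv, parameters: 590080}
  - {label: Batch Normalization 20, kind: batch_norm, parameters: 1024}
  - {label: De-Conv 8, kind: conv, parameters: 590080}
  - {label: Batch Normalization 21, kind: batch_norm, parameters: 1024}
  - {label: De-Conv 9, kind: conv, parameters: 295040}
  - {label: Batch Normalization 22, kind: batch_norm, parameters: 512}
  - {label: De-Conv 10, kind: conv, parameters: 147584}
  - {label: Batch Normalization 23, kind: batch_norm, parameters: 512}
  - {label: De-Conv 11, kind: conv, parameters: 73792}
  - {label: Batch Normalization 24, kind: batch_norm, parameters: 256}
  - {label: De-Conv 12, kind: conv, parameters: 36928}
  - {label: Batch Normalization 25, kind: batch_norm, parameters: 256}
  - {label: De-Conv 13, kind: conv, parameters: 577}
  - {label: Batch Normalization 26, kind: batch_norm, parameters: 4}
footer:
  total: 33393669
  trainable: 33377795
  non_trainable: 15874
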