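{
  "participant_id": "worker",
  "group": "cohort",
  "image_id": "image",
  "question_index": "order",
  "box_id": "bid",
  "x_min": "left",
  "y_min": "top",
  "width": "w",
  "height": "h",
  "time_seconds": "secs"
}
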