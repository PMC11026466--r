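{
  "name": "over_the_rainbow",
  "reference_hz": 261.626,
  "total_beats": 13,
  "notes": [
    {
      "expected_cents": 0,
      "duration_beats": 2,
      "exclude_from_pitch": false,
      "is_vibrato_note": true
    },
    {
      "expected_cents": 1200,
      "duration_beats": 2,
      "exclude_from_pitch": false,
      "is_vibrato_note": false
    },
    {
      "expected_cents": 1100,
      "duration_beats": 1,
      "exclude_from_pitch": false,
      "is_vibrato_note": false
    },
    {
      "expected_cents": 700,
      "duration_beats": 0.5,
      "exclude_from_pitch": true,
      "is_vibrato_note": false
    },
    {
      "expected_cents": 900,
      "duration_beats": 0.5,
      "exclude_from_pitch": false,
      "is_vibrato_note": false
    },
    {
      "expected_cents": 1100,
      "duration_beats": 1,
      "exclude_from_pitch": false,
      "is_vibrato_note": false
    },
    {
      "expected_cents": 1200,
      "duration_beats": 2,
      "exclude_from_pitch": false,
      "is_vibrato_note": false
    },
    {
      "expected_cents": 900,
      "duration_beats": 1.5,
      "exclude_from_pitch": false,
      "is_vibrato_note": false
    },
    {
      "expected_cents": 700,
      "duration_beats": 2.5,
      "exclude_from_pitch": false,
      "is_vibrato_note": false
    }
  ]
}
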