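{
  "name": "dont_worry_be_happy",
  "reference_hz": 261.626,
  "total_beats": 13,
  "notes": [
    {
      "expected_cents": 1200,
      "duration_beats": 1,
      "exclude_from_pitch": false,
      "is_vibrato_note": false
    },
    {
      "expected_cents": 1200,
      "duration_beats": 1,
      "exclude_from_pitch": false,
      "is_vibrato_note": false
    },
    {
      "expected_cents": 1200,
      "duration_beats": 1,
      "exclude_from_pitch": false,
      "is_vibrato_note": false
    },
    {
      "expected_cents": 900,
      "duration_beats": 1,
      "exclude_from_pitch": false,
      "is_vibrato_note": false
    },
    {
      "expected_cents": 1200,
      "duration_beats": 1.5,
      "exclude_from_pitch": false,
      "is_vibrato_note": false
    },
    {
      "expected_cents": 900,
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
      "duration_beats": 1,
      "exclude_from_pitch": false,
      "is_vibrato_note": false
    },
    {
      "expected_cents": 700,
      "duration_beats": 1,
      "exclude_from_pitch": false,
      "is_vibrato_note": false
    },
    {
      "expected_cents": 400,
      "duration_beats": 1,
      "exclude_from_pitch": false,
      "is_vibrato_note": false
    },
    {
      "expected_cents": 600,
      "duration_beats": 3,
      "exclude_from_pitch": false,
      "is_vibrato_note": true
    }
  ]
}
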