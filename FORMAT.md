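# The `.bin` recording format

A recording file is a concatenation of transport frames. Each frame is:

| field        | size      | content                                          |
|--------------|-----------|--------------------------------------------------|
| header length| 2 B, LSB-first | byte length of the JSON header              |
| header       | variable  | UTF-8 JSON: `{"device_id": "...", "checksum": N}` |
| block        | 4096 B    | one encoded block, zero-padded from 3925 B       |

`checksum` is the XOR fold of all 4096 block bytes, reduced to 8 bits. The
conventional filename is `<userID>_<ISO8601 start time>.bin`. Frames are
*not* chronologically ordered in the file (they follow the device's flash
layout); decoders must sort blocks by their sample counters.

## Block layout

A block is 25 rows of 157 bytes (3925 bytes, padded to the 4 KB flash block
with zeros):

* **Row 1**: `[4 B sample counter, LSB-first][2 B useful-bit count,
  LSB-first][151 B payload]`. The counter is the number of PPG samples
  produced by the drivers before the first PPG sample of this block; at
  100 Hz it fixes the block's position on the time axis.
* **Rows 2–25**: `[2 B useful-bit count][151+4 B payload]` (155 payload
  bytes; only the first row carries the counter).

The useful-bit count says how many payload bits in the row carry
information; the rest are empty. Tokens never straddle a row boundary — a
row is closed when the next token does not fit — so each row decodes
independently of the previous row's bit position.

## Token grammar

Payload bits are written most-significant-bit first. Each token is a
prefix-free descriptor followed by its payload:

| descriptor | token | payload | meaning |
|-----------|-------|---------|---------|
| `0`       | DD    | 8-bit signed | delta between this PPG sample and the previous one |
| `10`      | GB    | none    | garbage: artifact sample, value lost, counter advances |
| `110`     | AV    | 18-bit unsigned | absolute PPG value |
| `1110`    | SF    | 3-bit code + 8-bit signed | scale factor: value = previous + 2^(code+1) × quotient |
| `11110`   | SPO2  | 6-bit unsigned | saturation code = percent − 37, clamped to [0, 63]; 0 = artifact |
| `111110`  | MOVE  | 16-bit unsigned | per-epoch movement count |

Notes:

* The first data token of every block is an AV; the delta chain restarts
  there.
* A delta is DD-coded when it fits signed 8 bits; otherwise the smallest
  scale in {2, 4, …, 256} dividing it exactly with an 8-bit quotient is
  SF-coded (the quotient follows the scale code *without* a DD
  descriptor); with no exact factoring the sample is re-sent as AV. The
  codec is therefore lossless for all in-range samples.
* After a GB, the next sample is sent as AV to resynchronize.
* SPO2 and MOVE tokens are timestamped at the most recent preceding PPG
  sample in the stream.

## Worked example

PPG samples `1000, 1005, 1002, 1514, 1515, <artifact>, 1600` encode (in one
row) the Table-style token pattern `110 AV | 0 DD | 0 DD | 1110 SF DD |
0 DD | 10 | 110 AV`:

```
AV(1000)          110 000000001111101000
DD(+5)            0 00000101
DD(-3)            0 11111101          (two's complement)
SF(code 2 = ×8),
quotient +64      1110 010 01000000   (1514 − 1002 = 512 = 8 × 64)
DD(+1)            0 00000001
GB                10                  (the artifact)
AV(1600)          110 000000011001000000
```

86 useful bits; as row-1 bytes (after the counter `00 00 00 00` and the
useful-bit count `56 00` = 86):

```
C0 1F 40 15 FB C9 00 03 60 19 00
```

and the block's 8-bit XOR checksum is `148` (0x94).
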