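# Frame wire format

All multi-byte integers are big-endian. One encoded frame is serialized as:

| field          | type   | bytes | notes                               |
|----------------|--------|-------|-------------------------------------|
| sequenceNumber | uint32 | 4     | monotonically increasing            |
| rows           | uint16 | 2     | viewport rows                       |
| cols           | uint16 | 2     | viewport cols                       |
| quality        | uint8  | 1     | JPEG quality factor, 1..100         |
| keyframe       | uint8  | 1     | 1 = keyframe (all blocks present)   |
| blockCount     | uint16 | 2     | number of block records that follow |

followed by `blockCount` block records:

| field         | type   | bytes | notes                                  |
|---------------|--------|-------|----------------------------------------|
| blockRow      | uint16 | 2     | 1-based block-grid row                 |
| blockCol      | uint16 | 2     | 1-based block-grid col                 |
| payloadLength | uint32 | 4     | bytes of JPEG payload                  |
| payload       | bytes  | n     | baseline grayscale JPEG of the 8x8 block (edge blocks zero-padded before encoding, cropped on decode) |

The block grid is `ceil(rows/8) x ceil(cols/8)`. Block coordinates are
unique within a frame; a keyframe carries every block of the grid.

State diffs travel as XML (`state_diff.xsd`) or the equivalent JSON;
catalog and probe messages are JSON text. No other message types exist on
the wire.
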