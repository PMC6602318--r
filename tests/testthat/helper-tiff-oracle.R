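# Hex dumps of tiny TIFFs written by an independent third-party writer
# (Python tifffile), frozen here as byte-level oracles for tiff_read:
# a 3-page 5x7 grayscale stack, a 4x6 RGB page, and a big-endian page.

tiff_gray_hex <- paste0(
  "49492a00080000000e0000010400010000000700000001010400010000000500000002",
  "0103000100000008000000030103000100000001000000060103000100000001000000",
  "0e01020012000000b60000001101040001000000000100001501030001000000010000",
  "001601040001000000050000001701040001000000230000001a01050001000000d800",
  "00001b01050001000000e0000000280103000100000001000000310102000c000000e8",
  "000000240100007b227368617065223a205b352c20375d7d0000000000000000000000",
  "000000000000010000000100000001000000010000007469666666696c652e70790000",
  "00000000000000000000005f82c2d9cfeb0fa321d7d982f8bd1045b8e8cd4ea93d7d0a",
  "1df04213b6273b043b51de000e00000104000100000007000000010104000100000005",
  "0000000201030001000000080000000301030001000000010000000601030001000000",
  "010000000e01020012000000d201000011010400010000001002000015010300010000",
  "00010000001601040001000000050000001701040001000000230000001a0105000100",
  "0000f40100001b01050001000000fc010000280103000100000001000000310102000c",
  "00000004020000340200007b227368617065223a205b352c20375d7d00000000000000",
  "00000000000000000000010000000100000001000000010000007469666666696c652e",
  "7079002c787a32d04e1c40a67959aae97fb2ed80717b4c9b459a82f85f49c0babf7fdc",
  "a1e701000e000001040001000000070000000101040001000000050000000201030001",
  "000000080000000301030001000000010000000601030001000000010000000e010200",
  "12000000e2020000110104000100000020030000150103000100000001000000160104",
  "0001000000050000001701040001000000230000001a01050001000000040300001b01",
  "0500010000000c030000280103000100000001000000310102000c0000001403000000",
  "0000007b227368617065223a205b352c20375d7d000000000000000000000000000000",
  "0000010000000100000001000000010000007469666666696c652e7079002b8bedbf56",
  "8f07e860ef4c3700474dc7dbd0b090beab6878b300f0f5e664bfd87edb1f")

tiff_rgb_hex <- paste0(
  "49492a00080000000f0000010400010000000600000001010400010000000400000002",
  "01030003000000c2000000030103000100000001000000060103000100000002000000",
  "0e01020015000000c80000001101040001000000100100001501030001000000030000",
  "001601040001000000040000001701040001000000480000001a01050001000000ec00",
  "00001b01050001000000f40000001c0103000100000001000000280103000100000001",
  "000000310102000c000000fc000000000000000800080008007b227368617065223a20",
  "5b342c20362c20335d7d00000000000000000000000000000000010000000100000001",
  "000000010000007469666666696c652e70790000000000000000007310990879d3cfc3",
  "07b3cabaa627b9d849c4f72c0e7fdb163a4bf9dc2e79a805d9339d8a3812951420ebb9",
  "4cf1d6267bcf3a356c0ca33a673df53f0768ca5e016007d11fa8eb1e02")

tiff_be_hex <- paste0(
  "4d4d002a00000008000e01000004000000010000000701010004000000010000000501",
  "0200030000000100080000010300030000000100010000010600030000000100010000",
  "010e000200000012000000b60111000400000001000001000115000300000001000100",
  "00011600040000000100000005011700040000000100000023011a0005000000010000",
  "00d8011b000500000001000000e0012800030000000100010000013100020000000c00",
  "0000e8000000007b227368617065223a205b352c20375d7d0000000000000000000000",
  "000000000000000000010000000100000001000000017469666666696c652e70790000",
  "00000000000000000000005f82c2d9cfeb0fa321d7d982f8bd1045b8e8cd4ea93d7d0a",
  "1df04213b6273b043b51de")

tiff_gray_page1 <- matrix(c(95, 130, 194, 217, 207, 235, 15, 163, 33, 215, 217, 130, 248, 189, 16, 69, 184, 232, 205, 78, 169, 61, 125, 10, 29, 240, 66, 19, 182, 39, 59, 4, 59, 81, 222), nrow = 5, byrow = TRUE)
tiff_gray_page3 <- matrix(c(43, 139, 237, 191, 86, 143, 7, 232, 96, 239, 76, 55, 0, 71, 77, 199, 219, 208, 176, 144, 190, 171, 104, 120, 179, 0, 240, 245, 230, 100, 191, 216, 126, 219, 31), nrow = 5, byrow = TRUE)
tiff_rgb_luma <- matrix(c(61, 97, 177, 193, 94, 130, 101, 169, 90, 107, 78, 123, 44, 52, 127, 100, 102, 58, 85, 111, 160, 57, 100, 88), nrow = 4, byrow = TRUE)
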