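<?xml version="1.0" encoding="UTF-8"?>
<!-- Chained-job marker: each internal job step restarts the program. -->
<template id="linkrestart" pattern="\s*Link1:\s+Proceeding to internal job step.*"
          section="environment" jobstart="true">
  <record id="link1">\s*Link1:\s+Proceeding to internal job step number\s+{1I, g:jobstep}\..*</record>
</template>
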