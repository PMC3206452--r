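<?xml version="1.0" encoding="UTF-8"?>
<template id="pointgroup" pattern="\s*Full point group\s+.*" section="initialization">
  <record id="pg">\s*Full point group\s+{A, g:pointgroup}</record>
  <transform process="addDictRef" xpath=".//cml:scalar[@cmlx:temp='g:pointgroup']" value="cc:pointgroup"/>
</template>
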